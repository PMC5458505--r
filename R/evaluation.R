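#' Match detected intervals against reference marks
#'
#' Greedy one-to-one matching by temporal overlap, largest overlap first:
#' each reference interval is credited to at most one detection. TP =
#' matched references, FN = unmatched references, FP = unmatched
#' detections.
#'
#' @param detected,truth Data frames with onset_s, offset_s.
#' @return List: tp, fp, fn, matching (data frame of matched index pairs
#'   with their overlap in seconds).
#' @export
match_detections <- function(detected, truth) {
  nd <- nrow(detected); nt <- nrow(truth)
  matching <- data.frame(detected = integer(0), truth = integer(0),
                         overlap_s = numeric(0))
  if (nd && nt) {
    ov <- outer(seq_len(nd), seq_len(nt), function(i, j) {
      pmin(detected$offset_s[i], truth$offset_s[j]) -
        pmax(detected$onset_s[i], truth$onset_s[j])
    })
    ov[ov < 0] <- NA
    while (any(!is.na(ov))) {
      k <- arrayInd(which.max(ov), dim(ov))
      matching <- rbind(matching,
                        data.frame(detected = k[1], truth = k[2],
                                   overlap_s = ov[k[1], k[2]]))
      ov[k[1], ] <- NA
      ov[, k[2]] <- NA
    }
  }
  list(tp = nrow(matching), fp = nd - nrow(matching),
       fn = nt - nrow(matching), matching = matching)
}

#' Signal-detection-theory scores
#'
#' Hit rate tp/(tp+fn), false-alarm rate fp/(fp+tn), discriminability
#' d' = z(hit) - z(fa) and criterion C = -(z(hit)+z(fa))/2, with z the
#' standard normal quantile. When any rate is 0 or 1 the log-linear
#' correction is applied (0.5 added to every cell).
#'
#' @param tp,fp,fn,tn Confusion counts; tn is defined over candidate
#'   epochs (unmatched non-spindle candidates).
#' @return List of class \code{sdt_score}: tp, fp, fn, tn, hit_rate,
#'   fa_rate, d_prime, criterion_c, corrected.
#' @export
sdt_scores <- function(tp, fp, fn, tn) {
  if (tp + fn <= 0 || fp + tn <= 0) {
    stop("undefined rates: need tp+fn > 0 and fp+tn > 0")
  }
  hit <- tp / (tp + fn)
  fa <- fp / (fp + tn)
  corrected <- hit %in% c(0, 1) || fa %in% c(0, 1)
  if (corrected) {
    hit <- (tp + 0.5) / (tp + fn + 1)
    fa <- (fp + 0.5) / (fp + tn + 1)
  }
  zh <- stats::qnorm(hit); zf <- stats::qnorm(fa)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 hit_rate = hit, fa_rate = fa,
                 d_prime = zh - zf, criterion_c = -(zh + zf) / 2,
                 corrected = corrected),
            class = "sdt_score")
}

#' @export
print.sdt_score <- function(x, ...) {
  cat(sprintf(
    "<sdt_score> hit %.3f, FA %.3f, d' = %.2f, C = %.2f%s\n",
    x$hit_rate, x$fa_rate, x$d_prime, x$criterion_c,
    if (x$corrected) " (log-linear corrected)" else ""))
  invisible(x)
}

#' Score a spindle detector against reference marks on candidate epochs
#'
#' Convenience wrapper producing the full signal-detection score for a
#' detector: detections are matched one-to-one against the reference marks
#' (TP/FP/FN), and TN is the number of candidate epochs that overlap
#' neither a reference mark nor a detection (the natural "non-spindle"
#' unit of this pipeline).
#'
#' @param detected Detected events (onset_s, offset_s).
#' @param truth Reference marks.
#' @param candidates Candidate epochs defining the TN universe.
#' @return An \code{\link{sdt_scores}} result.
#' @export
score_detector <- function(detected, truth, candidates) {
  m <- match_detections(detected, truth)
  cand_free <- rep(TRUE, nrow(candidates))
  mark_hit <- function(iv) {
    vapply(seq_len(nrow(candidates)), function(i)
      any(iv$onset_s <= candidates$offset_s[i] &
            iv$offset_s >= candidates$onset_s[i]), logical(1))
  }
  if (nrow(truth)) cand_free <- cand_free & !mark_hit(truth)
  if (nrow(detected)) cand_free <- cand_free & !mark_hit(detected)
  sdt_scores(m$tp, m$fp, m$fn, sum(cand_free))
}
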