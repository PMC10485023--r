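#' Trapezoidal area under a growth curve
#'
#' @param time strictly increasing timepoints (minutes).
#' @param od optical density readings (OD600).
#' @return the trapezoidal AUC.
#' @export
trapz_auc <- function(time, od) {
  if (length(time) < 2) stop("need at least 2 timepoints")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  sum(diff(time) * (head(od, -1) + od[-1]) / 2)
}

#' Classify growth-curve phenotypes in a cohort
#'
#' Computes the trapezoidal AUC of each guide's induced and repressed growth
#' curve, normalizes by the cohort mean AUC per condition, and labels:
#'
#' * `active` — induced normalized AUC above `active_thresh` (the cell
#'   cleaved the toxin plasmid and grew under induction);
#' * `toxic` — induced normalized AUC below `toxic_thresh` *and* repressed
#'   growth also poor (below the cohort mean): the guide impairs growth even
#'   with the nuclease off;
#' * `inactive` — induced normalized AUC below `toxic_thresh` but normal
#'   repressed growth (grows only when the nuclease is repressed);
#' * `intermediate` — everything else.
#'
#' The default thresholds are quantile cutoffs of the induced-condition
#' normalized AUC distribution.
#'
#' @param od_induced,od_repressed numeric matrices (guides x timepoints)
#'   with guide rownames.
#' @param time shared timepoint vector, strictly increasing.
#' @param active_thresh induced normalized-AUC cutoff for active (1.64).
#' @param toxic_thresh induced normalized-AUC cutoff for toxic/inactive
#'   (0.121).
#' @return data.frame with per-guide AUCs, normalized AUCs, and `label`.
#' @export
classify_growth <- function(od_induced, od_repressed, time,
                            active_thresh = 1.64, toxic_thresh = 0.121) {
  if (length(time) < 2) stop("need at least 2 timepoints")
  stopifnot(ncol(od_induced) == length(time),
            ncol(od_repressed) == length(time),
            nrow(od_induced) == nrow(od_repressed))
  auc_i <- apply(od_induced, 1, function(v) trapz_auc(time, v))
  auc_r <- apply(od_repressed, 1, function(v) trapz_auc(time, v))
  norm_i <- auc_i / mean(auc_i)
  norm_r <- auc_r / mean(auc_r)
  label <- rep("intermediate", length(auc_i))
  label[norm_i > active_thresh] <- "active"
  low <- norm_i < toxic_thresh
  label[low & norm_r < 1] <- "toxic"
  label[low & norm_r >= 1] <- "inactive"
  data.frame(guide = rownames(od_induced), auc_induced = auc_i,
             auc_repressed = auc_r, auc_induced_norm = norm_i,
             auc_repressed_norm = norm_r, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}
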