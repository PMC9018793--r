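# Disease classification from blinded-observer histopathology abnormality
# counts: control mean + 2 SD threshold, k-of-m observer agreement, and
# Fisher's exact test on group disease frequencies.

#' Disease threshold from control abnormality counts
#'
#' `threshold = mean + 2 * SD` of the control counts (sample SD, n-1
#' denominator). A count qualifies as abnormal when strictly greater than
#' the threshold.
#'
#' @param control_counts numeric vector of control abnormality counts
#'   (>= 2 values).
#' @return the threshold.
#' @export
disease_threshold <- function(control_counts) {
  if (length(control_counts) < 2) {
    stop("need at least 2 control values for a threshold")
  }
  if (any(control_counts < 0)) stop("counts must be non-negative")
  mean(control_counts) + 2 * sd(control_counts)
}

#' Per-tissue disease thresholds from a pathology record table
#'
#' Control-lineage counts are pooled across observers by default
#' (`per_observer = TRUE` computes one threshold per tissue x observer).
#'
#' @param records data.frame with `animal_id`, `lineage`, `tissue`,
#'   `observer`, `abnormality_count`.
#' @param control_lineage lineage label of the control group.
#' @param per_observer compute observer-specific thresholds?
#' @return data.frame with `tissue` (and `observer` if requested) and
#'   `threshold`.
#' @export
compute_disease_thresholds <- function(records, control_lineage = "control",
                                       per_observer = FALSE) {
  ctl <- records[records$lineage == control_lineage, , drop = FALSE]
  if (!nrow(ctl)) stop("no records for control lineage '",
                       control_lineage, "'")
  key <- if (per_observer) list(tissue = ctl$tissue,
                                observer = ctl$observer)
  else list(tissue = ctl$tissue)
  agg <- aggregate(ctl$abnormality_count, by = key, FUN = disease_threshold)
  names(agg)[ncol(agg)] <- "threshold"
  agg
}

#' Classify animals as diseased by the k-of-m observer rule
#'
#' Each observer's count is compared with the tissue threshold (strictly
#' greater qualifies); an animal x tissue is diseased iff at least `k` of
#' the `m` observers qualify. Animals are additionally labeled by disease
#' burden: `none`, `single`, or `multiple` (more than one diseased
#' tissue).
#'
#' @param records pathology record data.frame (see
#'   [compute_disease_thresholds()]).
#' @param thresholds threshold table from [compute_disease_thresholds()]
#'   (pooled or per-observer).
#' @param k observers required to call disease (default 2).
#' @param m expected observers per animal x tissue (default 3).
#' @param missing_policy `"error"` (default) rejects animal x tissue
#'   entries with fewer than `m` observers; `"allow"` classifies with the
#'   observers present.
#' @return list with `calls` (animal x tissue rows: per-observer
#'   qualifying count, `diseased`, `threshold`) and `burden` (per animal:
#'   `n_diseases`, `status`).
#' @export
classify_animals <- function(records, thresholds, k = 2L, m = 3L,
                             missing_policy = c("error", "allow")) {
  missing_policy <- match.arg(missing_policy)
  per_observer <- "observer" %in% names(thresholds)
  idx <- if (per_observer) {
    match(paste(records$tissue, records$observer),
          paste(thresholds$tissue, thresholds$observer))
  } else {
    match(records$tissue, thresholds$tissue)
  }
  if (anyNA(idx)) stop("missing threshold for some tissue(s)")
  records$qualifies <- records$abnormality_count > thresholds$threshold[idx]
  records$.thr <- thresholds$threshold[idx]

  keyed <- split(records,
                 list(records$animal_id, records$tissue), drop = TRUE)
  calls <- do.call(rbind, lapply(keyed, function(g) {
    if (nrow(g) < m && missing_policy == "error") {
      stop("animal ", g$animal_id[1], " tissue ", g$tissue[1], " has ",
           nrow(g), " observer(s), expected ", m)
    }
    data.frame(animal_id = g$animal_id[1], lineage = g$lineage[1],
               tissue = g$tissue[1],
               n_observers = nrow(g),
               n_qualifying = sum(g$qualifies),
               diseased = sum(g$qualifies) >= k,
               threshold = g$.thr[1],
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  calls <- calls[order(calls$animal_id, calls$tissue), , drop = FALSE]

  nb <- aggregate(list(n_diseases = calls$diseased),
                  by = list(animal_id = calls$animal_id,
                            lineage = calls$lineage), FUN = sum)
  nb$status <- cut(nb$n_diseases, c(-1, 0, 1, Inf),
                   labels = c("none", "single", "multiple"))
  nb$status <- as.character(nb$status)
  list(calls = calls, burden = nb[order(nb$animal_id), , drop = FALSE])
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Enumerates the hypergeometric distribution with the observed margins
#' and sums the probabilities of all tables no more likely than the
#' observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == 2L))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(k, r1, r2, c1)
  obs <- dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Disease frequency report with Fisher tests against control
#'
#' Proportions of diseased animals per lineage and tissue, with the
#' two-sided Fisher exact p value of each non-control lineage against the
#' control lineage.
#'
#' @param calls the `calls` table from [classify_animals()].
#' @param control_lineage control lineage label.
#' @return data.frame with `lineage`, `tissue`, `n_animals`, `n_diseased`,
#'   `proportion`, `fisher_p` (NA for the control rows; `NaN`-free, empty
#'   lineages are flagged with `NA` proportion).
#' @export
disease_frequency_report <- function(calls, control_lineage = "control") {
  if (!control_lineage %in% calls$lineage) {
    stop("control lineage '", control_lineage, "' not present")
  }
  agg <- aggregate(list(n_diseased = calls$diseased,
                        n_animals = rep(1L, nrow(calls))),
                   by = list(lineage = calls$lineage,
                             tissue = calls$tissue), FUN = sum)
  agg$proportion <- ifelse(agg$n_animals > 0,
                           agg$n_diseased / agg$n_animals, NA_real_)
  agg$fisher_p <- NA_real_
  for (i in seq_len(nrow(agg))) {
    if (agg$lineage[i] == control_lineage) next
    j <- which(agg$lineage == control_lineage &
                 agg$tissue == agg$tissue[i])
    if (!length(j)) next
    tab <- matrix(c(agg$n_diseased[i], agg$n_animals[i] - agg$n_diseased[i],
                    agg$n_diseased[j], agg$n_animals[j] - agg$n_diseased[j]),
                  2, 2, byrow = TRUE)
    agg$fisher_p[i] <- fisher_exact_2x2(tab)
  }
  agg[order(agg$tissue, agg$lineage), , drop = FALSE]
}
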