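#' Normalized contamination rate of a mixed group
#'
#' For a join or bin whose member contigs best-match more than one reference
#' genome, the length-weighted impurity normalized so that an even split of
#' length across all matched references scores 100%:
#' `((Total_len - Max_len) / Total_len) / ((Num_polished - 1) / Num_polished)`.
#'
#' @param Total_len Total member length in bp.
#' @param Max_len Total length of members matching the dominant reference.
#' @param Num_polished Number of distinct matched references (>= 2; the rate
#'   is undefined for a pure group).
#' @return The contamination rate in `[0, 1]` (for the best-match-maximal
#'   case `Max_len >= Total_len / Num_polished`).
#' @examples
#' contamination_rate(100000, 60000, 2) # 0.8
#' @export
contamination_rate <- function(Total_len, Max_len, Num_polished) {
  if (Num_polished < 2) {
    stop("contamination rate undefined for fewer than 2 matched references")
  }
  if (!(Max_len > 0 && Max_len <= Total_len)) {
    stop("need 0 < Max_len <= Total_len")
  }
  ((Total_len - Max_len) / Total_len) /
    ((Num_polished - 1) / Num_polished)
}

#' Classify a join or bin against reference genomes
#'
#' Labels a group by its members' best-match references: one reference ->
#' `good`; several references that all share at least `ani_threshold` percent
#' ANI pairwise -> `problematic` (closely related subpopulations); any
#' reference pair below the threshold -> `contaminated`. Non-good groups also
#' get the normalized [contamination_rate()].
#'
#' @param members Data frame with columns `contig_id`, `length` (bp) and
#'   `best_ref` (best-match reference per member).
#' @param ani Data frame with columns `ref_a`, `ref_b`, `ani` (percent);
#'   looked up symmetrically. Required only for multi-reference groups.
#' @param ani_threshold ANI gate in percent (default 70).
#' @param group_id Optional group label.
#' @return A `group_evaluation` list: `group_id`, `label`, `matched_refs`,
#'   `Total_len`, `Max_len`, `Num_polished`, `contamination_rate` (NA for
#'   good groups).
#' @export
classify_group <- function(members, ani = NULL, ani_threshold = 70,
                           group_id = NA_character_) {
  stopifnot(all(c("contig_id", "length", "best_ref") %in% names(members)),
            nrow(members) > 0L)
  refs <- sort(unique(members$best_ref))
  total <- sum(members$length)
  per_ref <- tapply(members$length, members$best_ref, sum)
  max_len <- max(per_ref)
  k <- length(refs)
  if (k == 1L) {
    label <- "good"
    rate <- NA_real_
  } else {
    pairs <- utils::combn(refs, 2L)
    anis <- apply(pairs, 2L, function(p) lookup_ani(ani, p[1L], p[2L]))
    label <- if (all(anis >= ani_threshold)) "problematic" else "contaminated"
    rate <- contamination_rate(total, max_len, k)
  }
  structure(list(group_id = group_id, label = label, matched_refs = refs,
                 Total_len = total, Max_len = as.numeric(max_len),
                 Num_polished = k, contamination_rate = rate),
            class = "group_evaluation")
}

lookup_ani <- function(ani, a, b) {
  if (is.null(ani)) stop("missing ANI table for reference pair ", a, " / ", b)
  hit <- (ani$ref_a == a & ani$ref_b == b) | (ani$ref_a == b & ani$ref_b == a)
  if (!any(hit)) stop("missing ANI entry for reference pair ", a, " / ", b)
  ani$ani[which(hit)[1L]]
}

#' Confusion metrics over contig co-membership pairs
#'
#' Computes precision, recall, F1, specificity and accuracy from per-pair
#' truth/prediction labels: each row of `pairs` is one unordered contig pair,
#' `truth` saying whether the two contigs belong together in reality and
#' `pred` whether they were grouped together. When nothing is predicted
#' positive, precision (and F1) are reported as 0 with a warning.
#'
#' @param pairs Data frame with logical columns `truth` and `pred`, one row
#'   per unordered contig pair in the evaluation universe.
#' @return Named numeric vector: precision, recall, F1, specificity, accuracy.
#' @seealso [pair_labels()] to build `pairs` from group assignments.
#' @export
confusion_metrics <- function(pairs) {
  stopifnot(all(c("truth", "pred") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("empty pair universe")
  tp <- sum(pairs$truth & pairs$pred)
  fp <- sum(!pairs$truth & pairs$pred)
  fn <- sum(pairs$truth & !pairs$pred)
  tn <- sum(!pairs$truth & !pairs$pred)
  if (tp + fp == 0L) {
    warning("no predicted positive pairs; precision reported as 0")
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  specificity <- if (tn + fp == 0L) 0 else tn / (tn + fp)
  accuracy <- (tp + tn) / nrow(pairs)
  c(precision = precision, recall = recall, F1 = f1,
    specificity = specificity, accuracy = accuracy)
}

#' Pair labels from truth and predicted group assignments
#'
#' Builds the unordered contig-pair universe from contigs appearing in at
#' least one group (truth or predicted) and labels each pair by truth and
#' predicted co-membership; an unassigned contig is co-member of nothing.
#'
#' @param truth,pred Named character vectors mapping contig id to group id.
#' @return Data frame with columns `a`, `b`, `truth`, `pred`.
#' @export
pair_labels <- function(truth, pred) {
  universe <- sort(union(names(truth), names(pred)))
  if (length(universe) < 2L) stop("empty pair universe")
  idx <- utils::combn(universe, 2L)
  same <- function(map, a, b) {
    !is.na(map[a]) & !is.na(map[b]) & map[a] == map[b]
  }
  tmap <- truth[universe]; names(tmap) <- universe
  pmap <- pred[universe]; names(pmap) <- universe
  data.frame(a = idx[1L, ], b = idx[2L, ],
             truth = unname(same(tmap, idx[1L, ], idx[2L, ])),
             pred = unname(same(pmap, idx[1L, ], idx[2L, ])),
             stringsAsFactors = FALSE)
}

#' Reads per kilobase of genome per million mapped sample reads
#'
#' `RPKM = Nphage / (Lphage/1000) / (Nsample/1e6)`.
#'
#' @param Nphage Reads mapped to the genome.
#' @param Lphage Genome length in bp (>= 1).
#' @param Nsample Reads mapped to the whole contig set (> 0).
#' @return RPKM value.
#' @examples
#' rpkm(1000, 10000, 1e6) # 100
#' @export
rpkm <- function(Nphage, Lphage, Nsample) {
  stopifnot(Nphage >= 0, Lphage >= 1)
  if (Nsample == 0) stop("Nsample must be positive")
  Nphage / (Lphage / 1000) / (Nsample / 1e6)
}

#' Evaluate many groups and write a report
#'
#' Convenience wrapper: classifies each group with [classify_group()] and
#' returns a tidy table, optionally writing TSV and JSON reports.
#'
#' @param assignments Data frame: `group_id`, `contig_id`, `length`,
#'   `best_ref`.
#' @param ani ANI table as in [classify_group()].
#' @param ani_threshold ANI gate in percent (default 70).
#' @param tsv_path,json_path Optional output paths.
#' @return Data frame with one row per group: group_id, label, Total_len,
#'   Max_len, Num_polished, contamination_rate.
#' @export
evaluate_groups <- function(assignments, ani = NULL, ani_threshold = 70,
                            tsv_path = NULL, json_path = NULL) {
  stopifnot(all(c("group_id", "contig_id", "length", "best_ref") %in%
                  names(assignments)))
  out <- do.call(rbind, lapply(split(assignments, assignments$group_id),
                               function(g) {
    ev <- classify_group(g, ani, ani_threshold, group_id = g$group_id[1L])
    data.frame(group_id = ev$group_id, label = ev$label,
               Total_len = ev$Total_len, Max_len = ev$Max_len,
               Num_polished = ev$Num_polished,
               contamination_rate = ev$contamination_rate,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(tsv_path)) {
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  out
}
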