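# The walk model: a join walk is an ordered list of oriented contigs
# (id, forward?). Extending rightward from an oriented tip, the outward
# physical end is the tip's right end when forward, left end when reversed;
# a partner on side "left" enters the walk forward, a partner on side
# "right" enters reversed. Leftward extension mirrors this.

outward_side <- function(forward, direction) {
  if (direction == "right") {
    if (forward) "right" else "left"
  } else {
    if (forward) "left" else "right"
  }
}

orient_from_partner <- function(partner_side, direction) {
  if (direction == "right") partner_side == "left" else partner_side == "right"
}

oriented_seq <- function(contigs, id, forward) {
  s <- contigs$seq[match(id, contigs$id)]
  if (forward) s else reverse_complement(s)
}

#' Detect a self-circular query contig
#'
#' A query is self_circular when (case 1) its two ends are a valid path pair:
#' each end's only partner is the other end, i.e. the length-L prefix equals
#' the length-L suffix and matches nothing else; or (case 2) neither end has
#' any partner but the contig carries a shorter exact terminal repeat of
#' length `d >= minK` (direct terminal repeat left by assembling a circular
#' genome). The returned circular sequence has one repeat copy trimmed.
#'
#' @param query_id Query contig id.
#' @param contigs A `contig_set` containing the query.
#' @param index An `overlap_index` built on the same set.
#' @param params A [join_params()] object.
#' @return `NULL` when the query is not self-circular, otherwise a list with
#'   `case` (1 or 2), `trim` (bases trimmed), and `seq` (trimmed circular
#'   sequence).
#' @export
detect_self_circular <- function(query_id, contigs, index, params) {
  row <- match(query_id, contigs$id)
  if (is.na(row)) stop("query not in contig set: ", query_id)
  seq <- contigs$seq[row]
  len <- contigs$length[row]
  L <- params$L
  li <- end_index_of(index, query_id, "left")
  ri <- end_index_of(index, query_id, "right")
  if (!is.na(li) && !is.na(ri)) {
    # case 1: ends are each other's unique partner
    if (index$class[li] == "one_path_end" &&
        index$class[ri] == "one_path_end" &&
        identical(index$partners[[li]], ri)) {
      return(list(case = 1L, trim = L, seq = substr(seq, 1L, len - L)))
    }
    if (length(index$partners[[li]]) > 0L || length(index$partners[[ri]]) > 0L) {
      return(NULL)
    }
  }
  # case 2: unpartnered ends; longest exact terminal repeat d >= minK
  d <- longest_terminal_repeat(seq, params$minK)
  if (!is.na(d)) {
    return(list(case = 2L, trim = d, seq = substr(seq, 1L, len - d)))
  }
  NULL
}

# Longest d in [minK, len-1] with prefix(seq, d) == suffix(seq, d); exact
# match only (one mismatch disqualifies). Candidate starts are located by the
# occurrences of the minK-length prefix, then verified in full.
longest_terminal_repeat <- function(seq, minK) {
  len <- nchar(seq)
  if (len <= minK) return(NA_integer_)
  pref <- substr(seq, 1L, minK)
  if (grepl("N", pref, fixed = TRUE)) return(NA_integer_)
  hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(pref), Biostrings::DNAString(seq)))
  hits <- hits[hits >= 2L & hits <= len - minK + 1L]
  for (p in sort(hits)) { # smallest start = longest repeat
    d <- len - p + 1L
    if (substr(seq, p, len) == substr(seq, 1L, d)) return(d)
  }
  NA_integer_
}

#' Decide the next join at a contig end
#'
#' Applies the path-search rules at one outward contig end: stop at a dead
#' end (`no_match`) or an ambiguous junction (`multi_path_end`); at a
#' `one_path_end`, accept the unique partner iff its coverage is compatible
#' with the query's and the junction is spanned by enough read pairs,
#' otherwise fail; at a `two_paths_end`, accept the single candidate among
#' the two that passes both checks, and fail when zero or both pass.
#'
#' @param end_i Row index of the outward end in `index$ends`.
#' @param tip_id Contig id at the walk tip (spanning pairs are counted
#'   between this contig and the candidate).
#' @param query_cov Mean depth of the query contig (coverage ratios are
#'   always taken against the query).
#' @param index,contigs,coverage,linkage,params Shared engine state.
#' @return List with `decision` (`"accept"`, `"stop"` or `"fail"`), `reason`,
#'   and for accepts `partner` (row index in `index$ends`).
#' @export
next_join <- function(end_i, tip_id, query_cov, index, contigs,
                      coverage, linkage, params) {
  cls <- index$class[end_i]
  if (cls == "no_match") return(list(decision = "stop", reason = "no_match"))
  if (cls == "multi_path_end") {
    return(list(decision = "stop", reason = "multi_path"))
  }
  cand <- index$partners[[end_i]]
  check <- function(j) {
    cid <- index$ends$contig_id[j]
    cc <- coverage[cid]
    if (is.na(cc)) stop("no coverage entry for contig: ", cid)
    cov_ok <- coverage_compatible(query_cov, cc, params$cov_ratio_window)
    span_ok <- spanning_pairs(linkage, tip_id, cid) >= params$min_spanning_pairs
    c(cov = cov_ok, span = span_ok)
  }
  if (cls == "one_path_end") {
    ok <- check(cand)
    if (all(ok)) return(list(decision = "accept", partner = cand))
    return(list(decision = "fail",
                reason = paste(names(ok)[!ok], collapse = "+")))
  }
  # two_paths_end: the unique passing candidate wins; ties are conservative
  ok <- vapply(cand, function(j) all(check(j)), logical(1L))
  if (sum(ok) == 1L) return(list(decision = "accept", partner = cand[ok]))
  if (sum(ok) == 0L) return(list(decision = "fail", reason = "two_paths_none"))
  list(decision = "fail", reason = "two_paths_ambiguous")
}

extend_direction <- function(query_id, walk, direction, query_cov, index,
                             contigs, coverage, linkage, params,
                             allow_circular = TRUE) {
  circular <- FALSE
  failed <- FALSE
  accepted <- character()
  log <- list()
  repeat {
    tip <- if (direction == "right") walk[[length(walk)]] else walk[[1L]]
    side <- outward_side(tip$forward, direction)
    end_i <- end_index_of(index, tip$id, side)
    if (is.na(end_i)) break # contig shorter than L: dead end
    d <- next_join(end_i, tip$id, query_cov, index, contigs,
                   coverage, linkage, params)
    if (d$decision != "accept") {
      if (d$decision == "fail") failed <- TRUE
      log <- c(log, list(list(tip = tip$id, direction = direction,
                              decision = d$decision, reason = d$reason)))
      break
    }
    p_id <- index$ends$contig_id[d$partner]
    p_side <- index$ends$side[d$partner]
    fwd <- orient_from_partner(p_side, direction)
    if (p_id == query_id) {
      # loop back to the query's opposite end in consistent orientation
      closes <- fwd && allow_circular &&
        ((direction == "right" && p_side == "left") ||
         (direction == "left" && p_side == "right"))
      if (closes) {
        circular <- TRUE
        log <- c(log, list(list(tip = tip$id, direction = direction,
                                decision = "accept", reason = "circularized")))
      }
      break
    }
    if (p_id %in% vapply(walk, `[[`, character(1L), "id")) {
      log <- c(log, list(list(tip = tip$id, direction = direction,
                              decision = "stop", reason = "revisit")))
      break
    }
    log <- c(log, list(list(tip = tip$id, direction = direction,
                            decision = "accept", reason = "joined",
                            candidate = p_id)))
    node <- list(id = p_id, forward = fwd)
    if (direction == "right") walk <- c(walk, list(node))
    else walk <- c(list(node), walk)
    accepted <- c(accepted, p_id)
    if (circular) break
  }
  list(walk = walk, circular = circular, failed = failed,
       accepted = accepted, log = log)
}

#' Extend one query contig and classify it
#'
#' Runs self-circular detection, then extends the query from both ends via
#' [next_join()] until each direction stops, fails, or loops back to the
#' query's opposite end. A walk never uses a contig twice; revisiting a
#' non-query contig stops that direction.
#'
#' Categories: `self_circular`; `extended_circular` (looped back);
#' `extended_partial` (extended without circularizing); `extended_failed`
#' (at least one end has a partner but nothing could be joined);
#' `orphan_end` (no partners at either end).
#'
#' @inheritParams detect_self_circular
#' @param coverage Named depth vector (must cover the query and every
#'   candidate).
#' @param linkage A `linkage_evidence`.
#' @return An `extension_result` list: `query_id`, `category`, `walk`
#'   (list of `(id, forward)`; the query only for self_circular; empty for
#'   orphan_end/extended_failed), `joined_seq` (NULL when absent),
#'   `trim_note`, `left_ids`, `right_ids`, `log`.
#' @export
extend_query <- function(query_id, contigs, index, coverage, linkage, params) {
  row <- match(query_id, contigs$id)
  if (is.na(row)) stop("query not in contig set: ", query_id)
  query_cov <- coverage[query_id]
  if (is.na(query_cov)) stop("no coverage entry for query: ", query_id)

  sc <- detect_self_circular(query_id, contigs, index, params)
  if (!is.null(sc)) {
    return(structure(list(query_id = query_id, category = "self_circular",
                          walk = list(list(id = query_id, forward = TRUE)),
                          joined_seq = sc$seq, trim_note = sc$trim,
                          left_ids = character(), right_ids = character(),
                          log = list()),
                     class = "extension_result"))
  }

  walk0 <- list(list(id = query_id, forward = TRUE))
  r <- extend_direction(query_id, walk0, "right", query_cov, index, contigs,
                        coverage, linkage, params)
  if (r$circular) {
    seq <- merge_walk_sequence(contigs, r$walk, params$L, circular = TRUE)
    return(structure(list(query_id = query_id, category = "extended_circular",
                          walk = r$walk, joined_seq = seq,
                          trim_note = params$L,
                          left_ids = character(), right_ids = r$accepted,
                          log = r$log),
                     class = "extension_result"))
  }
  l <- extend_direction(query_id, r$walk, "left", query_cov, index, contigs,
                        coverage, linkage, params,
                        allow_circular = length(r$accepted) == 0L)
  walk <- l$walk
  if (l$circular) {
    seq <- merge_walk_sequence(contigs, walk, params$L, circular = TRUE)
    return(structure(list(query_id = query_id, category = "extended_circular",
                          walk = walk, joined_seq = seq, trim_note = params$L,
                          left_ids = l$accepted, right_ids = r$accepted,
                          log = c(r$log, l$log)),
                     class = "extension_result"))
  }
  extended <- length(r$accepted) + length(l$accepted) > 0L
  if (extended) {
    seq <- merge_walk_sequence(contigs, walk, params$L, circular = FALSE)
    return(structure(list(query_id = query_id, category = "extended_partial",
                          walk = walk, joined_seq = seq, trim_note = 0L,
                          left_ids = l$accepted, right_ids = r$accepted,
                          log = c(r$log, l$log)),
                     class = "extension_result"))
  }
  li <- end_index_of(index, query_id, "left")
  ri <- end_index_of(index, query_id, "right")
  has_partner <- (!is.na(li) && length(index$partners[[li]]) > 0L) ||
    (!is.na(ri) && length(index$partners[[ri]]) > 0L)
  category <- if (has_partner) "extended_failed" else "orphan_end"
  structure(list(query_id = query_id, category = category, walk = list(),
                 joined_seq = NULL, trim_note = 0L,
                 left_ids = character(), right_ids = character(),
                 log = c(r$log, l$log)),
            class = "extension_result")
}

#' Merge an oriented walk into one sequence
#'
#' Concatenates the oriented member sequences, dropping one copy of each
#' internal exact L-overlap; a circular walk additionally trims the final
#' L-overlap that closes the loop, so a linear merge has length
#' `sum(lengths) - (n-1)*L` and a circular one `sum(lengths) - n*L`.
#'
#' @param contigs A `contig_set`.
#' @param walk List of `(id, forward)` oriented members.
#' @param L Overlap length.
#' @param circular Whether the walk closes on itself.
#' @return The merged DNA string.
#' @export
merge_walk_sequence <- function(contigs, walk, L, circular = FALSE) {
  seqs <- vapply(walk, function(w) oriented_seq(contigs, w$id, w$forward),
                 character(1L))
  n <- length(seqs)
  if (n == 0L) stop("empty walk")
  out <- seqs[1L]
  if (n > 1L) {
    for (i in 2L:n) {
      if (substr(out, nchar(out) - L + 1L, nchar(out)) !=
          substr(seqs[i], 1L, L)) {
        stop("internal consistency violation: overlap mismatch between walk ",
             "members ", walk[[i - 1L]]$id, " and ", walk[[i]]$id)
      }
      out <- paste0(out, substr(seqs[i], L + 1L, nchar(seqs[i])))
    }
  }
  if (circular) {
    if (substr(out, nchar(out) - L + 1L, nchar(out)) !=
        substr(out, 1L, L)) {
      stop("internal consistency violation: circular walk does not close")
    }
    out <- substr(out, 1L, nchar(out) - L)
  }
  out
}

#' Enforce cross-query path uniqueness
#'
#' Post-processes all extension results: (a) when a contig is claimed by the
#' accepted walks of two or more distinct final sequences (distinct member
#' sets), every query involved becomes `extended_failed`; (b) when the two
#' directional extensions of one query pulled in distinct contigs whose
#' sequences are near-duplicates (canonical k-mer containment >= `containment`
#' at word size `k`), that query becomes `extended_failed` — both ends of the
#' query converged into closely related (strain-variant) sequence.
#'
#' @param results List of `extension_result` objects.
#' @param contigs A `contig_set`.
#' @param k Word size for the near-duplicate check (default 31).
#' @param containment Containment threshold in (0, 1] (default 0.9).
#' @return The updated list of results.
#' @export
resolve_cross_query_conflicts <- function(results, contigs, k = 31L,
                                          containment = 0.9) {
  joined <- which(vapply(results, function(r)
    r$category %in% c("extended_circular", "extended_partial"), logical(1L)))
  # (b) strain-variant convergence within one query
  for (i in joined) {
    r <- results[[i]]
    if (r$category != "extended_partial") next
    if (length(r$left_ids) == 0L || length(r$right_ids) == 0L) next
    hit <- FALSE
    for (a in r$left_ids) {
      for (b in setdiff(r$right_ids, a)) {
        ca <- contigs$seq[match(a, contigs$id)]
        cb <- contigs$seq[match(b, contigs$id)]
        if (kmer_containment(ca, cb, k) >= containment) hit <- TRUE
      }
    }
    if (hit) results[[i]] <- fail_result(r, "convergent_paths")
  }
  # (a) one contig claimed by two distinct final sequences
  joined <- which(vapply(results, function(r)
    r$category %in% c("extended_circular", "extended_partial"), logical(1L)))
  if (length(joined) > 1L) {
    keys <- vapply(results[joined], function(r)
      paste(sort(vapply(r$walk, `[[`, character(1L), "id")), collapse = "\r"),
      character(1L))
    members <- lapply(results[joined], function(r)
      vapply(r$walk, `[[`, character(1L), "id"))
    all_ids <- unique(unlist(members))
    bad_keys <- character()
    for (cid in all_ids) {
      in_keys <- unique(keys[vapply(members, function(m) cid %in% m,
                                    logical(1L))])
      if (length(in_keys) > 1L) bad_keys <- union(bad_keys, in_keys)
    }
    for (j in seq_along(joined)) {
      if (keys[j] %in% bad_keys) {
        results[[joined[j]]] <- fail_result(results[[joined[j]]],
                                            "shared_path")
      }
    }
  }
  results
}

fail_result <- function(r, reason) {
  r$category <- "extended_failed"
  r$walk <- list()
  r$joined_seq <- NULL
  r$trim_note <- 0L
  r$log <- c(r$log, list(list(tip = r$query_id, direction = "resolve",
                              decision = "fail", reason = reason)))
  r
}

# Canonical k-mer containment between two sequences: shared distinct
# canonical k-mers over the smaller distinct-k-mer set.
kmer_containment <- function(a, b, k = 31L) {
  ka <- canonical_kmers(a, k)
  kb <- canonical_kmers(b, k)
  if (length(ka) == 0L || length(kb) == 0L) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

canonical_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  km <- substring(s, 1:(n - k + 1L), k:n)
  km <- unique(km[!grepl("N", km, fixed = TRUE)])
  if (length(km) == 0L) return(character())
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

#' Run the full contig-joining analysis
#'
#' Orchestrates the four processing steps: build the end overlap index over
#' the whole assembly, load the two join-validity signals (coverage table and
#' paired-read linkage), extend and classify every query, and enforce
#' cross-query path uniqueness. Queries are processed in descending length
#' then id, so results are deterministic for identical inputs.
#'
#' @param assembly_fasta Path to the FASTA of all contigs in the assembly.
#' @param query_fasta Path to the FASTA of query contigs (ids must exist in
#'   the assembly).
#' @param coverage_tsv Path to the two-column coverage table.
#' @param mapping Path to SAM/BAM of the read set mapped to all contigs, or a
#'   prebuilt `linkage_evidence`.
#' @param assembler,maxK,minK Assembly parameters (see [join_params()]).
#' @param cov_ratio_window,min_spanning_pairs,mm_max Validation thresholds
#'   (see [join_params()]).
#' @param outdir Optional output directory; when given, [write_outputs()] is
#'   called on the result.
#' @return A `cobra_result` list: `results` (per-query `extension_result`s),
#'   `summary` (per-query data frame), `counts` (category tally), `params`,
#'   `contigs`, `index`.
#' @export
run_cobra <- function(assembly_fasta, query_fasta, coverage_tsv, mapping,
                      assembler, maxK, minK,
                      cov_ratio_window = c(0.5, 2),
                      min_spanning_pairs = 1L, mm_max = 2L,
                      outdir = NULL) {
  params <- join_params(assembler, maxK, minK, cov_ratio_window,
                        min_spanning_pairs, mm_max)
  coverage <- load_coverage(coverage_tsv)
  contigs <- load_contigs(assembly_fasta, coverage = coverage)
  queries <- load_contigs(query_fasta)
  missing <- setdiff(queries$id, contigs$id)
  if (length(missing) > 0L) {
    stop("query id(s) absent from assembly FASTA: ",
         paste(missing, collapse = ", "))
  }
  linkage <- if (inherits(mapping, "linkage_evidence")) mapping else
    collect_spanning_pairs(mapping, mm_max = params$mm_max)
  index <- build_overlap_index(contigs, params$L)
  ord <- order(-queries$length, queries$id)
  qids <- queries$id[ord]
  results <- lapply(qids, extend_query, contigs = contigs, index = index,
                    coverage = coverage, linkage = linkage, params = params)
  results <- resolve_cross_query_conflicts(results, contigs)
  names(results) <- qids
  out <- structure(list(results = results,
                        summary = summarize_results(results, contigs, params),
                        counts = category_counts(results),
                        params = params, contigs = contigs, index = index),
                   class = "cobra_result")
  if (!is.null(outdir)) write_outputs(out, outdir)
  out
}

category_counts <- function(results) {
  lev <- c("self_circular", "extended_circular", "extended_partial",
           "extended_failed", "orphan_end")
  table(factor(vapply(results, `[[`, character(1L), "category"), levels = lev))
}

summarize_results <- function(results, contigs, params) {
  rows <- lapply(results, function(r) {
    n_members <- length(r$walk)
    final_len <- if (!is.null(r$joined_seq)) nchar(r$joined_seq) else
      contigs$length[match(r$query_id, contigs$id)]
    data.frame(query_id = r$query_id, category = r$category,
               joined_id = joined_id_for(r),
               n_contigs_joined = n_members,
               final_length = final_len,
               members = paste(vapply(r$walk, function(w)
                 paste0(w$id, if (w$forward) "+" else "-"), character(1L)),
                 collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(query_id = character(), category = character(),
                      joined_id = character(), n_contigs_joined = integer(),
                      final_length = integer(), members = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

joined_id_for <- function(r) {
  switch(r$category,
         self_circular = paste0(r$query_id, "_self_circular"),
         extended_circular = paste0(r$query_id, "_extended_circular"),
         extended_partial = paste0(r$query_id, "_extended"),
         r$query_id)
}

#' Canonical rotation of a circular sequence
#'
#' Rotates a circular sequence to the lexicographically smallest rotation of
#' the smaller of the sequence and its reverse complement, giving a stable
#' representative for comparing circular sequences.
#'
#' @param seq Circular DNA string (repeat already trimmed).
#' @return The canonical rotation.
#' @export
canonical_rotation <- function(seq) {
  best <- function(s) {
    k <- least_rotation_start(s)
    substr(paste0(s, s), k + 1L, k + nchar(s))
  }
  min(best(seq), best(reverse_complement(seq)))
}

# 0-based start of the lexicographically least rotation (two-pointer
# duel over the doubled string)
least_rotation_start <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(0L)
  b <- utf8ToInt(paste0(s, s))
  i <- 0L; j <- 1L; k <- 0L
  while (i < n && j < n && k < n) {
    a <- b[i + k + 1L]; c <- b[j + k + 1L]
    if (a == c) {
      k <- k + 1L
    } else if (a > c) {
      i <- i + k + 1L
      if (i <= j) i <- j + 1L
      k <- 0L
    } else {
      j <- j + k + 1L
      if (j <= i) j <- i + 1L
      k <- 0L
    }
  }
  min(i, j)
}
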