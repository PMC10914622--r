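#' Load contigs from a FASTA file
#'
#' Reads an assembly FASTA into a contig set. Sequences are uppercased; the
#' record order of the file is preserved so that downstream iteration is
#' deterministic. The contig id is the first whitespace-delimited token of the
#' header line.
#'
#' @param fasta_path Path to a FASTA file (single- or multi-line records).
#' @param coverage Optional named numeric vector of mean sequencing depth per
#'   contig id (see [load_coverage()]); attached to the set when given.
#' @return A `contig_set`: a data frame with columns `id`, `seq`, `length`
#'   and `coverage` (NA when no coverage table was supplied).
#' @export
load_contigs <- function(fasta_path, coverage = NULL) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  dss <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(dss))
  seqs <- toupper(as.character(dss))
  names(seqs) <- NULL
  if (any(duplicated(ids))) {
    stop("duplicate contig id(s) in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(ids))) stop("empty contig id in ", fasta_path)
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN character(s) in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  contig_set(ids, seqs, coverage = coverage)
}

#' Construct a contig set from vectors
#'
#' @param id Character vector of unique contig ids.
#' @param seq Character vector of uppercase DNA sequences over ACGTN.
#' @param coverage Optional named numeric vector of mean depths.
#' @return A `contig_set` data frame.
#' @export
contig_set <- function(id, seq, coverage = NULL) {
  stopifnot(length(id) == length(seq), !any(duplicated(id)))
  cov <- rep(NA_real_, length(id))
  if (!is.null(coverage)) {
    cov <- unname(coverage[id])
  }
  out <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                    length = nchar(seq), coverage = cov,
                    stringsAsFactors = FALSE)
  class(out) <- c("contig_set", "data.frame")
  out
}

#' Expected contig end-sequence length for an assembler
#'
#' De Bruijn assemblers leave a fixed-length shared sequence at the ends of
#' contigs that abut in the assembly graph: the largest k-mer size (maxK) for
#' metaSPAdes and MEGAHIT, and maxK-1 for IDBA_UD.
#'
#' @param assembler One of `"metaspades"`, `"megahit"`, `"idba_ud"`.
#' @param maxK Largest k-mer size used in the assembly (>= 2).
#' @return Integer end-sequence length L.
#' @examples
#' end_length_for("metaspades", 99) # 99
#' end_length_for("idba_ud", 100)   # 99
#' @export
end_length_for <- function(assembler, maxK) {
  if (!is.numeric(maxK) || length(maxK) != 1L || maxK < 2) {
    stop("maxK must be a single integer >= 2")
  }
  switch(match.arg(assembler, c("metaspades", "megahit", "idba_ud")),
         metaspades = as.integer(maxK),
         megahit = as.integer(maxK),
         idba_ud = as.integer(maxK) - 1L)
}

#' Reverse complement of a DNA string
#'
#' Standard reverse complement over the ACGTN alphabet; N maps to N.
#'
#' @param seq A DNA string (character scalar or vector) over ACGTN.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) stop("invalid character in DNA string")
  out <- vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1L), USE.NAMES = FALSE)
  out
}

#' Join-engine parameters
#'
#' Bundles the assembler-determined end length together with the tunable
#' validation thresholds used while walking joins.
#'
#' @param assembler One of `"metaspades"`, `"megahit"`, `"idba_ud"`.
#' @param maxK Largest k-mer size used by the assembler.
#' @param minK Smallest k-mer size; lower bound for the shorter terminal
#'   repeat accepted in self_circular detection. Must satisfy `minK < maxK`.
#' @param cov_ratio_window Inclusive `(lo, hi)` window for the
#'   candidate/query coverage ratio; default `c(0.5, 2)`.
#' @param min_spanning_pairs Minimum read pairs that must span a join
#'   (default 1).
#' @param mm_max Maximum mismatches per mapped read when counting spanning
#'   pairs (default 2).
#' @return A `join_params` list with the derived end length `L`.
#' @export
join_params <- function(assembler, maxK, minK,
                        cov_ratio_window = c(0.5, 2),
                        min_spanning_pairs = 1L,
                        mm_max = 2L) {
  assembler <- match.arg(assembler, c("metaspades", "megahit", "idba_ud"))
  if (!(minK < maxK)) stop("minK must be smaller than maxK")
  if (!(cov_ratio_window[1] <= 1 && 1 <= cov_ratio_window[2])) {
    stop("cov_ratio_window must contain 1")
  }
  if (min_spanning_pairs < 1L) stop("min_spanning_pairs must be >= 1")
  if (mm_max < 0L) stop("mm_max must be >= 0")
  structure(list(assembler = assembler,
                 maxK = as.integer(maxK), minK = as.integer(minK),
                 L = end_length_for(assembler, maxK),
                 cov_ratio_window = as.numeric(cov_ratio_window),
                 min_spanning_pairs = as.integer(min_spanning_pairs),
                 mm_max = as.integer(mm_max)),
            class = "join_params")
}

# Two physical contig ends are partners when one contig can be glued after
# the other across an exact L-length overlap, in either orientation:
#   opposite sides (right,left): equal L-mers;
#   same sides (right,right)/(left,left): reverse-complement L-mers.
# An end L-mer containing N never matches (an ambiguous base cannot certify
# an exact de Bruijn overlap). Palindromic L-mers are matched once.

#' Build the reverse-complement-aware contig end overlap index
#'
#' Registers the length-`L` prefix (left end) and suffix (right end) of every
#' contig, computes each end's partner set under rc-aware matching, and
#' classifies every end as `no_match`, `one_path_end`, `two_paths_end` or
#' `multi_path_end`. `two_paths_end` is reserved for an end A partnered with
#' exactly two ends B and C where B and C are each partnered exclusively
#' with A; two partners without that exclusivity fall into `multi_path_end`.
#'
#' Contigs shorter than `L` stay in the set (and can still be queried, ending
#' up as `orphan_end`) but contribute no ends; their ids are reported in the
#' `excluded` field.
#'
#' @param contigs A `contig_set`.
#' @param L End-sequence length (see [end_length_for()]).
#' @return An `overlap_index` list with fields `ends` (data frame: contig_id,
#'   side, end_seq), `partners` (list of integer index vectors, ordered by
#'   (contig_id, side)), `class` (character vector), `L` and `excluded`.
#' @export
build_overlap_index <- function(contigs, L) {
  if (L <= 0) stop("L must be positive")
  L <- as.integer(L)
  ok <- contigs$length >= L
  excluded <- contigs$id[!ok]
  cs <- contigs[ok, , drop = FALSE]
  n <- nrow(cs)
  if (n == 0L) {
    ends <- data.frame(contig_id = character(), side = character(),
                       end_seq = character(), stringsAsFactors = FALSE)
    return(structure(list(ends = ends, partners = list(),
                          class = character(), L = L, excluded = excluded),
                     class = "overlap_index"))
  }
  ends <- data.frame(
    contig_id = rep(cs$id, each = 2L),
    side = rep(c("left", "right"), times = n),
    end_seq = as.vector(rbind(substr(cs$seq, 1L, L),
                              substr(cs$seq, cs$length - L + 1L, cs$length))),
    stringsAsFactors = FALSE)
  m <- nrow(ends)
  has_n <- grepl("N", ends$end_seq, fixed = TRUE)
  rc <- character(m)
  rc[!has_n] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ends$end_seq[!has_n])))
  by_seq <- split(seq_len(m)[!has_n], ends$end_seq[!has_n])
  partners <- vector("list", m)
  for (i in seq_len(m)) {
    if (has_n[i]) {
      partners[[i]] <- integer()
      next
    }
    same <- by_seq[[ends$end_seq[i]]]
    opp <- same[ends$side[same] != ends$side[i]]      # opposite side, equal
    rcm <- by_seq[[rc[i]]]
    if (is.null(rcm)) rcm <- integer()
    sam <- rcm[ends$side[rcm] == ends$side[i]]        # same side, rc
    p <- setdiff(unique(c(opp, sam)), i)
    # deterministic partner order: by (contig_id, side)
    partners[[i]] <- p[order(ends$contig_id[p], ends$side[p])]
  }
  cls <- classify_ends(partners)
  structure(list(ends = ends, partners = partners, class = cls,
                 L = L, excluded = excluded),
            class = "overlap_index")
}

classify_ends <- function(partners) {
  deg <- lengths(partners)
  cls <- rep("multi_path_end", length(partners))
  cls[deg == 0L] <- "no_match"
  cls[deg == 1L] <- "one_path_end"
  two <- which(deg == 2L)
  for (i in two) {
    bc <- partners[[i]]
    if (all(vapply(partners[bc], function(p) identical(p, i), logical(1L)))) {
      cls[i] <- "two_paths_end"
    }
  }
  cls
}

#' Locate an end's row in an overlap index
#'
#' @param index An `overlap_index`.
#' @param contig_id Contig id.
#' @param side `"left"` or `"right"`.
#' @return Integer row index into `index$ends`, or `NA` if the contig was
#'   excluded (shorter than L).
#' @export
end_index_of <- function(index, contig_id, side) {
  hit <- which(index$ends$contig_id == contig_id & index$ends$side == side)
  if (length(hit) == 0L) NA_integer_ else hit
}

#' Partner ends of a contig end
#'
#' @inheritParams end_index_of
#' @return Data frame of partner ends (contig_id, side, end_seq); zero rows
#'   when the end matches nothing.
#' @export
partners_of <- function(index, contig_id, side) {
  i <- end_index_of(index, contig_id, side)
  if (is.na(i)) return(index$ends[0L, , drop = FALSE])
  index$ends[index$partners[[i]], , drop = FALSE]
}

#' Classification of a contig end
#'
#' @inheritParams end_index_of
#' @return One of `"no_match"`, `"one_path_end"`, `"two_paths_end"`,
#'   `"multi_path_end"`, or `NA` for an excluded contig.
#' @export
end_class_of <- function(index, contig_id, side) {
  i <- end_index_of(index, contig_id, side)
  if (is.na(i)) NA_character_ else index$class[i]
}
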