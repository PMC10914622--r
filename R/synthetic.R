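# Ground-truthed synthetic communities: genomes with direct terminal
# repeats (circular genomes in linear representation), subpopulation
# variants at fixed per-base mutation rates, repeat-induced fragmentation
# into contigs with exact L-length shared end sequences, and error-free
# paired reads emitted directly as SAM from known placements.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform integer in [lo, hi]; safe when lo == hi (sample() would otherwise
# treat a scalar as 1:x)
rint <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}

mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- round(rate * n)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k) # without replacement
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  # transitions and transversions equiprobable: uniform over the other three
  repl <- vapply(bases[pos], function(b) {
    i <- sample.int(3L, 1L)
    substr(alt[[b]], i, i)
  }, character(1L))
  bases[pos] <- repl
  paste(bases, collapse = "")
}

#' Simulate a ground-truthed viral community
#'
#' Generates five genome categories: circular genomes carrying a direct
#' terminal repeat (DTR) of 100-200 bp, pairs of an original genome and a
#' variant mutated at 1%, 3% or 5% of bases, and triplets of an original
#' plus a 3%- and a 5%-mutant. Originals are retained for every mutated
#' category, so the total genome count is
#' `n_dtr + 2*(n_1p + n_3p + n_5p) + 3*n_three`. Each genome is assigned a
#' uniform random sequencing depth in `depth_range`.
#'
#' @param n_dtr,n_1p,n_3p,n_5p,n_three Category sizes; defaults are the
#'   composite-benchmark design (500, 500, 500, 500, 300 giving 4,400
#'   genomes).
#' @param genome_len_range Genome length range in bp (default 5-50 kb, the
#'   typical phage size range).
#' @param depth_range Per-genome depth range (default 10-100x).
#' @param dtr_len_range DTR length range (default 100-200 bp).
#' @param seed Integer seed; identical seeds give byte-identical communities.
#' @return A `synthetic_community` list with `genomes` (data frame: id, seq,
#'   length, is_circular, circumference, dtr_len, parent_id, mutation_rate,
#'   depth). For DTR genomes `seq` is the linear representation, i.e. the
#'   circular genome plus one repeat copy, and `circumference` the true
#'   circular length.
#' @export
simulate_community <- function(n_dtr = 500L, n_1p = 500L, n_3p = 500L,
                               n_5p = 500L, n_three = 300L,
                               genome_len_range = c(5000L, 50000L),
                               depth_range = c(10, 100),
                               dtr_len_range = c(100L, 200L),
                               seed = 1L) {
  stopifnot(n_dtr >= 0L, n_1p >= 0L, n_3p >= 0L, n_5p >= 0L, n_three >= 0L)
  set.seed(seed)
  rows <- list()
  glen <- function() rint(genome_len_range[1L], genome_len_range[2L])
  add <- function(id, seq, is_circular, circumference, dtr_len,
                  parent_id, mutation_rate) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, seq = seq, length = nchar(seq), is_circular = is_circular,
      circumference = circumference, dtr_len = dtr_len,
      parent_id = parent_id, mutation_rate = mutation_rate,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_dtr)) {
    g <- random_dna(glen())
    d <- rint(dtr_len_range[1L], dtr_len_range[2L])
    add(sprintf("dtr_%04d", i), paste0(g, substr(g, 1L, d)),
        TRUE, nchar(g), d, NA_character_, 0)
  }
  pair_cat <- function(prefix, n, rate) {
    for (i in seq_len(n)) {
      g <- random_dna(glen())
      base_id <- sprintf("%s_%04d", prefix, i)
      add(base_id, g, FALSE, NA_integer_, 0L, NA_character_, 0)
      add(paste0(base_id, "_m"), mutate_seq(g, rate), FALSE, NA_integer_,
          0L, base_id, rate)
    }
  }
  pair_cat("sub1p", n_1p, 0.01)
  pair_cat("sub3p", n_3p, 0.03)
  pair_cat("sub5p", n_5p, 0.05)
  for (i in seq_len(n_three)) {
    g <- random_dna(glen())
    base_id <- sprintf("three_%04d", i)
    add(base_id, g, FALSE, NA_integer_, 0L, NA_character_, 0)
    add(paste0(base_id, "_m3"), mutate_seq(g, 0.03), FALSE, NA_integer_,
        0L, base_id, 0.03)
    add(paste0(base_id, "_m5"), mutate_seq(g, 0.05), FALSE, NA_integer_,
        0L, base_id, 0.05)
  }
  genomes <- do.call(rbind, rows)
  if (is.null(genomes)) {
    genomes <- data.frame(id = character(), seq = character(),
                          length = integer(), is_circular = logical(),
                          circumference = integer(), dtr_len = integer(),
                          parent_id = character(), mutation_rate = numeric())
  }
  rownames(genomes) <- NULL
  genomes$depth <- if (nrow(genomes) > 0L)
    stats::runif(nrow(genomes), depth_range[1L], depth_range[2L]) else numeric()
  structure(list(genomes = genomes, seed = seed),
            class = "synthetic_community")
}

circ_substr <- function(g, start0, end0) {
  # 0-based half-open coordinates on a circle of length nchar(g)
  gg <- paste0(g, g)
  substr(gg, start0 + 1L, end0)
}

#' Fragment community genomes into overlap-sharing contigs
#'
#' Emulates de Bruijn assembler breakpoints: plants repeats per `repeat_spec`
#' and fragments each genome so that adjacent fragments share exactly the
#' L-length end sequence. Supported fragmentation sources:
#'
#' * `n_random_breaks` — a count or `(lo, hi)` range of breakpoints per
#'   genome at unique positions (breaks whose other graph parties are not in
#'   the community); such genomes are recoverable by re-joining.
#' * `within_repeats` — this many eligible linear genomes receive an internal
#'   duplication: a segment is copied to a second locus and the genome is cut
#'   at the repeat boundaries into flank/repeat/flank contigs, creating
#'   two_paths ends (the repeat contig is required twice by the true walk, so
#'   full recovery is impossible — as in real assemblies).
#' * `shared_regions` — this many genome pairs receive a common planted
#'   region; the shared contig is emitted once, creating inter-genome
#'   two_paths ends.
#'
#' Circular (DTR) genomes are fragmented around the circle; with zero breaks
#' they stay a single contig carrying their DTR.
#'
#' @param community A `synthetic_community`.
#' @param L End-sequence length shared by adjacent fragments.
#' @param repeat_spec List with any of `n_random_breaks` (scalar or range;
#'   default `c(1, 3)`), `within_repeats` (default 0), `shared_regions`
#'   (default 0), `repeat_len` (range, default `c(300, 500)`).
#' @param seed Integer seed.
#' @return A `fragmented_assembly` list: `contigs` (a `contig_set`), `truth`
#'   (contig_id, genome_id, start, end, strand; 0-based half-open on the
#'   genome, `end` may exceed the circumference for origin-spanning circular
#'   fragments), `placements` (like truth but with one row per placement;
#'   shared contigs have two), `genomes` (possibly repeat-modified), `L`.
#' @export
fragment_at_repeats <- function(community, L,
                                repeat_spec = list(), seed = 1L) {
  set.seed(seed)
  spec <- utils::modifyList(list(n_random_breaks = c(1L, 3L),
                                 within_repeats = 0L, shared_regions = 0L,
                                 repeat_len = c(300L, 500L)), repeat_spec)
  genomes <- community$genomes
  if ((spec$within_repeats > 0L || spec$shared_regions > 0L) &&
      spec$repeat_len[1L] < L) {
    stop("repeat_len must be >= L")
  }
  min_frag <- max(2L * L, 300L)
  contigs <- list(); placements <- list()
  add_contig <- function(id, seq, genome_id, start, end) {
    contigs[[length(contigs) + 1L]] <<- data.frame(
      id = id, seq = seq, stringsAsFactors = FALSE)
    placements[[length(placements) + 1L]] <<- data.frame(
      contig_id = id, genome_id = genome_id, start = start, end = end,
      strand = "+", stringsAsFactors = FALSE)
  }
  add_placement <- function(id, genome_id, start, end) {
    placements[[length(placements) + 1L]] <<- data.frame(
      contig_id = id, genome_id = genome_id, start = start, end = end,
      strand = "+", stringsAsFactors = FALSE)
  }

  linear <- which(!genomes$is_circular)
  eligible <- linear[genomes$length[linear] >=
                       4L * min_frag + 2L * spec$repeat_len[2L]]
  rep_g <- utils::head(eligible, spec$within_repeats)
  remaining <- setdiff(eligible, rep_g)
  n_sh <- min(spec$shared_regions, length(remaining) %/% 2L)
  shared_pairs <- if (n_sh > 0L)
    matrix(utils::head(remaining, 2L * n_sh), ncol = 2L, byrow = TRUE) else
    matrix(integer(), ncol = 2L)
  handled <- c(rep_g, as.vector(shared_pairs))

  # within-genome duplication: X | R | Y | R | Z cut into 4 contigs
  for (gi in rep_g) {
    g <- genomes$seq[gi]; len <- genomes$length[gi]
    id <- genomes$id[gi]
    r <- rint(spec$repeat_len[1L], spec$repeat_len[2L])
    a1 <- min_frag
    a2 <- a1 + r + min_frag
    if (a2 + r + min_frag > len) stop("genome too short for planted repeat")
    R <- substr(g, a1 + 1L, a1 + r)
    g <- paste0(substr(g, 1L, a2), R, substr(g, a2 + r + 1L, len))
    genomes$seq[gi] <- g
    add_contig(paste0(id, "_c1"), substr(g, 1L, a1 + L), id, 0L, a1 + L)
    add_contig(paste0(id, "_rep"), substr(g, a1 + 1L, a1 + r), id, a1, a1 + r)
    add_contig(paste0(id, "_c2"), substr(g, a1 + r - L + 1L, a2 + L),
               id, a1 + r - L, a2 + L)
    add_contig(paste0(id, "_c3"), substr(g, a2 + r - L + 1L, len),
               id, a2 + r - L, len)
  }

  # cross-genome shared region: one shared contig, flanks per genome
  for (k in seq_len(nrow(shared_pairs))) {
    gi <- shared_pairs[k, 1L]; gj <- shared_pairs[k, 2L]
    r <- rint(spec$repeat_len[1L], spec$repeat_len[2L])
    ai <- min_frag; aj <- min_frag + 37L # offset so flanks differ in length
    g1 <- genomes$seq[gi]; g2 <- genomes$seq[gj]
    S <- substr(g1, ai + 1L, ai + r)
    g2 <- paste0(substr(g2, 1L, aj), S,
                 substr(g2, aj + r + 1L, genomes$length[gj]))
    genomes$seq[gj] <- g2
    id1 <- genomes$id[gi]; id2 <- genomes$id[gj]
    sid <- paste0(id1, "_", id2, "_shared")
    add_contig(paste0(id1, "_c1"), substr(g1, 1L, ai + L), id1, 0L, ai + L)
    add_contig(sid, S, id1, ai, ai + r)
    add_placement(sid, id2, aj, aj + r)
    add_contig(paste0(id1, "_c2"),
               substr(g1, ai + r - L + 1L, genomes$length[gi]),
               id1, ai + r - L, genomes$length[gi])
    add_contig(paste0(id2, "_c1"), substr(g2, 1L, aj + L), id2, 0L, aj + L)
    add_contig(paste0(id2, "_c2"),
               substr(g2, aj + r - L + 1L, genomes$length[gj]),
               id2, aj + r - L, genomes$length[gj])
  }

  # plain breakpoint fragmentation for everything else
  n_breaks_for <- function(max_breaks) {
    nb <- spec$n_random_breaks
    if (length(nb) == 1L) nb <- c(nb, nb)
    min(rint(nb[1L], nb[2L]), max_breaks)
  }
  for (gi in setdiff(seq_len(nrow(genomes)), handled)) {
    id <- genomes$id[gi]
    if (genomes$is_circular[gi]) {
      circ <- genomes$circumference[gi]
      g <- substr(genomes$seq[gi], 1L, circ)
      max_b <- max(0L, circ %/% min_frag)
      k <- n_breaks_for(max_b)
      if (k == 0L) {
        add_contig(paste0(id, "_c1"), genomes$seq[gi], id, 0L,
                   genomes$length[gi])
        next
      }
      b <- sort(pick_spaced(circ, k, min_frag, circular = TRUE))
      nxt <- c(b[-1L], b[1L] + circ)
      for (j in seq_len(k)) {
        add_contig(sprintf("%s_c%d", id, j),
                   circ_substr(g, b[j], nxt[j] + L), id, b[j], nxt[j] + L)
      }
    } else {
      len <- genomes$length[gi]
      g <- genomes$seq[gi]
      max_b <- max(0L, len %/% min_frag - 1L)
      k <- n_breaks_for(max_b)
      if (k == 0L) {
        add_contig(paste0(id, "_c1"), g, id, 0L, len)
        next
      }
      b <- sort(pick_spaced(len, k, min_frag, circular = FALSE))
      bounds <- c(0L, b, len)
      for (j in seq_len(k + 1L)) {
        e <- if (j == k + 1L) bounds[j + 1L] else bounds[j + 1L] + L
        add_contig(sprintf("%s_c%d", id, j), substr(g, bounds[j] + 1L, e),
                   id, bounds[j], e)
      }
    }
  }

  contigs <- do.call(rbind, contigs)
  placements <- do.call(rbind, placements)
  rownames(contigs) <- rownames(placements) <- NULL
  truth <- placements[!duplicated(placements$contig_id), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(contigs = contig_set(contigs$id, contigs$seq),
                 truth = truth, placements = placements,
                 genomes = genomes, L = L),
            class = "fragmented_assembly")
}

# k breakpoints in [0, n) at least min_gap apart (also from the ends for
# linear sequences); rejection sampling, deterministic under the caller's seed
pick_spaced <- function(n, k, min_gap, circular) {
  for (try in 1:200) {
    lo <- if (circular) 0L else min_gap
    hi <- if (circular) n - 1L else n - min_gap
    if (hi - lo + 1L < k) break
    b <- sort(sample(lo:hi, k))
    gaps <- diff(c(b, if (circular) b[1L] + n else n + min_gap))
    if (all(gaps >= min_gap) && (circular || b[1L] >= min_gap)) return(b)
  }
  stop("could not place ", k, " breakpoints with spacing ", min_gap,
       " on length ", n)
}

#' Simulate paired reads and emit alignments from known placements
#'
#' Draws error-free (or low-error) 126 bp read pairs uniformly from each
#' genome at its assigned depth, assigns each read to the contig that fully
#' contains it, and writes a SAM file directly from the known coordinates
#' (no aligner involved) with exact NM tags, plus the per-contig coverage
#' table computed from the same placements. Reads crossing a fragment
#' junction beyond the shared end sequence are unplaceable on a single
#' contig and are left out of the SAM (their mate, if placed, is written
#' with the mate-unmapped flag).
#'
#' @param community A `synthetic_community` (provides depths and genome
#'   sequences).
#' @param fragments The matching `fragmented_assembly`.
#' @param read_len Read length in bp (default 126).
#' @param insert_mean,insert_sd Insert size distribution (defaults 300, 30);
#'   inserts are clamped to at least `2*read_len`.
#' @param error_rate Per-base substitution error rate (default 0).
#' @param sam_path Output SAM path (default: tempfile).
#' @param coverage_path Optional path for the two-column coverage TSV.
#' @param seed Integer seed.
#' @return A `simulated_reads` list: `sam`, `coverage` (named vector),
#'   `coverage_path`, `n_pairs` (pairs drawn), `n_records` (SAM records).
#' @export
simulate_reads <- function(community, fragments, read_len = 126L,
                           insert_mean = 300, insert_sd = 30,
                           error_rate = 0, sam_path = tempfile(fileext = ".sam"),
                           coverage_path = NULL, seed = 1L) {
  set.seed(seed)
  genomes <- fragments$genomes
  contigs <- fragments$contigs
  placements <- fragments$placements
  depths <- stats::setNames(community$genomes$depth, community$genomes$id)
  recs <- character(0L)
  cov_bases <- stats::setNames(numeric(nrow(contigs)), contigs$id)
  n_pairs_total <- 0L
  rec_list <- vector("list", nrow(genomes))

  for (gi in seq_len(nrow(genomes))) {
    gid <- genomes$id[gi]
    circular <- genomes$is_circular[gi]
    eff <- if (circular) genomes$circumference[gi] else genomes$length[gi]
    g <- if (circular) substr(genomes$seq[gi], 1L, eff) else genomes$seq[gi]
    gg <- if (circular) paste0(g, g) else g
    depth <- depths[[gid]]
    n_pairs <- max(0L, round(depth * eff / (2 * read_len)))
    if (n_pairs == 0L) next
    n_pairs_total <- n_pairs_total + n_pairs
    pl <- placements[placements$genome_id == gid, , drop = FALSE]
    ins <- pmax(2L * read_len,
                round(stats::rnorm(n_pairs, insert_mean, insert_sd)))
    if (!circular) ins <- pmin(ins, eff)
    s <- if (circular) sample.int(eff, n_pairs, replace = TRUE) - 1L else
      vapply(ins, function(i) sample.int(eff - i + 1L, 1L) - 1L, integer(1L))
    qn <- sprintf("%s_p%06d", gid, seq_len(n_pairs))
    s1 <- s                      # fwd mate start (0-based)
    s2 <- s + ins - read_len     # rev mate start
    m1 <- place_reads(pl, s1, eff, circular, read_len)
    m2 <- place_reads(pl, s2, eff, circular, read_len)
    mk <- function(ms, os, start, rev, mate_flag) {
      ok <- !is.na(ms$contig)
      if (!any(ok)) return(character())
      other_ok <- !is.na(os$contig)[ok]
      seq <- substring(gg, start[ok] + 1L, start[ok] + read_len)
      nm <- integer(sum(ok))
      if (error_rate > 0) {
        ne <- stats::rbinom(sum(ok), read_len, error_rate)
        for (i in which(ne > 0L)) seq[i] <- mutate_seq(seq[i],
                                                       ne[i] / read_len)
        nm <- ne
      }
      flag <- 1L + mate_flag + (if (rev) 16L else 0L) +
        ifelse(other_ok, if (rev) 0L else 32L, 8L)
      rnext <- ifelse(!other_ok, "*",
                      ifelse(os$contig[ok] == ms$contig[ok], "=",
                             os$contig[ok]))
      pnext <- ifelse(other_ok, os$pos[ok], 0L)
      sprintf("%s\t%d\t%s\t%d\t60\t%dM\t%s\t%d\t0\t%s\t*\tNM:i:%d",
              qn[ok], flag, ms$contig[ok], ms$pos[ok], read_len,
              rnext, pnext, seq, nm)
    }
    lines <- c(mk(m1, m2, s1, FALSE, 64L), mk(m2, m1, s2, TRUE, 128L))
    placed <- c(m1$contig, m2$contig)
    placed <- placed[!is.na(placed)]
    if (length(placed) > 0L) {
      tab <- table(placed)
      cov_bases[names(tab)] <- cov_bases[names(tab)] +
        as.numeric(tab) * read_len
    }
    rec_list[[gi]] <- lines
  }
  recs <- unlist(rec_list)
  if (is.null(recs)) recs <- character()
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs$id, contigs$length))
  writeLines(c(hdr, recs), sam_path)
  cov <- cov_bases / contigs$length
  names(cov) <- contigs$id
  if (!is.null(coverage_path)) {
    utils::write.table(
      data.frame(id = names(cov), depth = sprintf("%.4f", cov)),
      coverage_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  structure(list(sam = sam_path, coverage = cov,
                 coverage_path = coverage_path,
                 n_pairs = n_pairs_total, n_records = length(recs)),
            class = "simulated_reads")
}

# First placement fully containing each read (probing circular genomes one
# circumference later as well); NA when a read is unplaceable on any single
# contig (it crossed a junction beyond the shared end sequence).
place_reads <- function(pl, starts, eff, circular, read_len) {
  n <- length(starts)
  contig <- rep(NA_character_, n)
  pos <- rep(NA_integer_, n)
  probes <- if (circular) list(starts, starts + eff, starts - eff) else
    list(starts)
  for (t in probes) {
    for (pi in seq_len(nrow(pl))) {
      hit <- is.na(contig) & pl$start[pi] <= t & t + read_len <= pl$end[pi]
      contig[hit] <- pl$contig_id[pi]
      pos[hit] <- as.integer(t[hit] - pl$start[pi] + 1L)
    }
  }
  list(contig = contig, pos = pos)
}

#' Write a named set of sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 80L)
  invisible(path)
}
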