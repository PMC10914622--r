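# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

h_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

h_rc <- function(s) rejoinr::reverse_complement(s)

# A linear genome cut into n_frag contigs sharing exact L-overlaps, plus
# uniform coverage and full pairwise linkage between adjacent contigs.
h_chain <- function(n_frag, frag_len = 400L, L = 99L, cov = 20,
                    prefix = "ctg") {
  glen <- n_frag * frag_len - (n_frag - 1L) * L
  g <- h_dna(glen)
  starts <- (seq_len(n_frag) - 1L) * (frag_len - L) + 1L
  seqs <- substring(g, starts, starts + frag_len - 1L)
  ids <- sprintf("%s%02d", prefix, seq_len(n_frag))
  adj <- if (n_frag > 1L)
    data.frame(a = ids[-n_frag], b = ids[-1L], count = 5L) else
    data.frame(a = character(), b = character(), count = integer())
  list(genome = g, ids = ids, seqs = stats::setNames(seqs, ids),
       contigs = rejoinr::contig_set(ids, seqs),
       coverage = stats::setNames(rep(cov, n_frag), ids),
       linkage = rejoinr::linkage_from_pairs(adj))
}

# A circular genome of circumference circ cut into n_frag ring contigs.
h_ring <- function(n_frag, circ = 1200L, L = 99L, cov = 20, prefix = "ring") {
  g <- h_dna(circ)
  gg <- paste0(g, g)
  step <- circ %/% n_frag
  starts <- (seq_len(n_frag) - 1L) * step
  ends <- c(starts[-1L], circ) + L
  seqs <- substring(gg, starts + 1L, ends)
  ids <- sprintf("%s%02d", prefix, seq_len(n_frag))
  adj <- data.frame(a = ids, b = c(ids[-1L], ids[1L]), count = 5L)
  adj <- adj[adj$a != adj$b, , drop = FALSE]
  list(genome = g, ids = ids,
       contigs = rejoinr::contig_set(ids, seqs),
       coverage = stats::setNames(rep(cov, n_frag), ids),
       linkage = rejoinr::linkage_from_pairs(adj))
}

h_params <- function(L = 99L, ...) {
  rejoinr::join_params("metaspades", maxK = L, minK = 21L, ...)
}

h_write_fasta <- function(seqs, dir = tempdir(),
                          name = paste0("fx", as.integer(stats::runif(1, 1, 1e8)), ".fasta")) {
  path <- file.path(dir, name)
  rejoinr::write_fasta(seqs, path)
  path
}

# Minimal SAM writer for handcrafted alignment fixtures.
h_sam <- function(targets, records, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(targets), targets))
  writeLines(c(hdr, records), path)
  path
}

h_sam_rec <- function(qname, flag, rname, pos, cigar, seq,
                      rnext = "*", pnext = 0L, nm = NULL) {
  tag <- if (is.null(nm)) "" else sprintf("\tNM:i:%d", nm)
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t%s\t*%s",
          qname, flag, rname, pos, cigar, rnext, pnext, seq, tag)
}

# Brute-force rc-aware partner oracle over all end pairs; independent of the
# overlap index implementation.
h_partner_oracle <- function(contigs, L) {
  ends <- list()
  for (i in seq_len(nrow(contigs))) {
    if (contigs$length[i] < L) next
    s <- contigs$seq[i]
    ends[[length(ends) + 1L]] <- list(id = contigs$id[i], side = "left",
                                      seq = substr(s, 1L, L))
    ends[[length(ends) + 1L]] <- list(id = contigs$id[i], side = "right",
                                      seq = substr(s, nchar(s) - L + 1L,
                                                   nchar(s)))
  }
  n <- length(ends)
  partners <- vector("list", n)
  for (i in seq_len(n)) partners[[i]] <- integer()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ei <- ends[[i]]; ej <- ends[[j]]
      if (grepl("N", ei$seq, fixed = TRUE) ||
          grepl("N", ej$seq, fixed = TRUE)) next
      hit <- if (ei$side != ej$side) ei$seq == ej$seq else
        ei$seq == h_rc(ej$seq)
      if (hit) partners[[i]] <- union(partners[[i]], j)
    }
  }
  list(ends = ends, partners = partners)
}
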