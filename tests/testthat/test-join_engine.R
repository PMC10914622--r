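test_that("self_circular case 1 detects an exact L-length end pair", {
  set.seed(31)
  L <- 99L
  S <- h_dna(L)
  seq <- paste0(S, h_dna(800), S)
  cs <- contig_set("q", seq)
  idx <- build_overlap_index(cs, L)
  sc <- detect_self_circular("q", cs, idx, h_params(L))
  expect_equal(sc$case, 1L)
  expect_equal(sc$trim, L)
  expect_equal(nchar(sc$seq), nchar(seq) - L)
})

test_that("self_circular case 2 detects shorter and longer terminal repeats", {
  set.seed(32)
  L <- 99L
  params <- h_params(L)
  # 30 bp repeat: shorter than L, >= minK
  R30 <- h_dna(30)
  s30 <- paste0(R30, h_dna(700), R30)
  cs <- contig_set("q", s30)
  sc <- detect_self_circular("q", cs, build_overlap_index(cs, L), params)
  expect_equal(sc$case, 2L)
  expect_equal(sc$trim, 30L)
  expect_equal(nchar(sc$seq), nchar(s30) - 30L)

  # 150 bp direct terminal repeat (longer than L): ends unmatched at L, but
  # the terminal repeat still certifies circularity
  R150 <- h_dna(150)
  s150 <- paste0(R150, h_dna(900), R150)
  cs <- contig_set("q", s150)
  sc <- detect_self_circular("q", cs, build_overlap_index(cs, L), params)
  expect_equal(sc$trim, 150L)
  expect_equal(nchar(sc$seq), nchar(s150) - 150L)

  # brute-force oracle for the longest exact terminal repeat
  brute <- function(s, minK) {
    n <- nchar(s)
    for (d in (n - 1L):minK) {
      if (substr(s, 1, d) == substr(s, n - d + 1L, n)) return(d)
    }
    NA_integer_
  }
  for (dlen in c(21L, 60L, 120L, 199L)) {
    R <- h_dna(dlen)
    s <- paste0(R, h_dna(500), R)
    cs <- contig_set("q", s)
    sc <- detect_self_circular("q", cs, build_overlap_index(cs, L), params)
    expect_equal(sc$trim, brute(s, params$minK))
  }
  # one mismatch in the repeat disqualifies
  R <- h_dna(40)
  Rbad <- paste0(substr(R, 1, 20), "A" , substr(R, 22, 40))
  if (Rbad == R) Rbad <- paste0(substr(R, 1, 20), "C", substr(R, 22, 40))
  s <- paste0(R, h_dna(500), Rbad)
  cs <- contig_set("q", s)
  expect_null(detect_self_circular("q", cs, build_overlap_index(cs, L),
                                   params))
})

test_that("next_join applies coverage and spanning rules at one- and two-path ends", {
  set.seed(33)
  L <- 50L
  S <- h_dna(L)
  A <- paste0(h_dna(300), S)
  B <- paste0(S, h_dna(300))
  C <- paste0(S, h_dna(280))
  params <- h_params(L)

  # one_path_end: accept with compatible coverage and spanning pairs
  cs1 <- contig_set(c("A", "B"), c(A, B))
  idx1 <- build_overlap_index(cs1, L)
  cov <- c(A = 20, B = 21, C = 90)
  lnk <- linkage_from_pairs(data.frame(a = c("A", "A"), b = c("B", "C"),
                                       count = 3L))
  ei <- end_index_of(idx1, "A", "right")
  d <- next_join(ei, "A", cov["A"], idx1, cs1, cov, lnk, params)
  expect_equal(d$decision, "accept")
  expect_equal(idx1$ends$contig_id[d$partner], "B")

  # one_path_end: incompatible coverage fails
  d2 <- next_join(ei, "A", cov["A"], idx1, cs1, c(A = 20, B = 90), lnk, params)
  expect_equal(d2$decision, "fail")
  expect_match(d2$reason, "cov")

  # one_path_end: no spanning pairs fails
  d3 <- next_join(ei, "A", cov["A"], idx1, cs1, cov,
                  linkage_from_pairs(data.frame(a = character(),
                                                b = character(),
                                                count = integer())), params)
  expect_equal(d3$decision, "fail")
  expect_match(d3$reason, "span")

  # two_paths_end: the single candidate passing both checks wins
  cs2 <- contig_set(c("A", "B", "C"), c(A, B, C))
  idx2 <- build_overlap_index(cs2, L)
  ei2 <- end_index_of(idx2, "A", "right")
  expect_equal(idx2$class[ei2], "two_paths_end")
  d4 <- next_join(ei2, "A", 20, idx2, cs2, c(A = 20, B = 20, C = 5),
                  lnk, params)
  expect_equal(d4$decision, "accept")
  expect_equal(idx2$ends$contig_id[d4$partner], "B")

  # both candidates pass -> conservative fail
  d5 <- next_join(ei2, "A", 20, idx2, cs2, c(A = 20, B = 20, C = 20),
                  lnk, params)
  expect_equal(d5$decision, "fail")
  expect_equal(d5$reason, "two_paths_ambiguous")

  # candidate without a coverage entry is a hard error
  expect_error(next_join(ei, "A", 20, idx1, cs1, c(A = 20), lnk, params),
               "coverage")
})

test_that("extend_query classifies chains, rings, orphans and failures", {
  set.seed(34)
  L <- 99L
  params <- h_params(L)

  fx <- h_chain(3, frag_len = 400, L = L)
  idx <- build_overlap_index(fx$contigs, L)
  r <- extend_query(fx$ids[1], fx$contigs, idx, fx$coverage, fx$linkage,
                    params)
  expect_equal(r$category, "extended_partial")
  expect_length(r$walk, 3L)
  expect_equal(r$joined_seq, fx$genome)

  # ring: extension loops back to the query and circularizes
  rg <- h_ring(3, circ = 1200, L = L)
  ridx <- build_overlap_index(rg$contigs, L)
  rr <- extend_query(rg$ids[1], rg$contigs, ridx, rg$coverage, rg$linkage,
                     params)
  expect_equal(rr$category, "extended_circular")
  expect_equal(nchar(rr$joined_seq), 1200L)
  expect_equal(canonical_rotation(rr$joined_seq),
               canonical_rotation(rg$genome))

  # orphan: both ends unique in the index
  lone <- contig_set(c(fx$ids, "lone"), c(fx$seqs, lone = h_dna(500)))
  lidx <- build_overlap_index(lone, L)
  ro <- extend_query("lone", lone, lidx, c(fx$coverage, lone = 20),
                     fx$linkage, params)
  expect_equal(ro$category, "orphan_end")
  expect_length(ro$walk, 0L)

  # failed: a partner exists but coverage is incompatible
  bad_cov <- fx$coverage
  bad_cov[fx$ids[2]] <- 500
  rf <- extend_query(fx$ids[1], fx$contigs, idx, bad_cov, fx$linkage, params)
  expect_equal(rf$category, "extended_failed")
  expect_length(rf$walk, 0L)
  expect_null(rf$joined_seq)
})

test_that("extension joins across reverse-complemented contigs", {
  set.seed(35)
  L <- 99L
  fx <- h_chain(3, frag_len = 400, L = L)
  seqs <- fx$seqs
  seqs[2] <- h_rc(seqs[2]) # middle contig stored reverse-complemented
  cs <- contig_set(names(seqs), seqs)
  idx <- build_overlap_index(cs, L)
  r <- extend_query(fx$ids[1], cs, idx, fx$coverage, fx$linkage, h_params(L))
  expect_equal(r$category, "extended_partial")
  expect_equal(r$joined_seq, fx$genome)
  expect_false(r$walk[[2]]$forward)
})

test_that("merge_walk_sequence obeys the length law and checks overlaps", {
  set.seed(36)
  L <- 99L
  fx <- h_chain(2, frag_len = 300, L = L)
  walk <- lapply(fx$ids, function(id) list(id = id, forward = TRUE))
  out <- merge_walk_sequence(fx$contigs, walk, L, circular = FALSE)
  expect_equal(nchar(out), 501L) # 2*300 - 99

  one <- merge_walk_sequence(fx$contigs, walk[1], L, circular = FALSE)
  expect_equal(one, fx$seqs[[1]])

  rg <- h_ring(3, circ = 603, L = L) # three ring contigs of ~300 bp
  rwalk <- lapply(rg$ids, function(id) list(id = id, forward = TRUE))
  circ <- merge_walk_sequence(rg$contigs, rwalk, L, circular = TRUE)
  expect_equal(nchar(circ), 603L) # 3*300 - 3*99

  # length law on random walks
  for (n in 2:5) {
    fxn <- h_chain(n, frag_len = 350, L = L)
    w <- lapply(fxn$ids, function(id) list(id = id, forward = TRUE))
    expect_equal(nchar(merge_walk_sequence(fxn$contigs, w, L, FALSE)),
                 sum(nchar(fxn$seqs)) - (n - 1L) * L)
  }

  # inconsistent overlap is a hard error
  bad <- contig_set(c("a", "b"), c(h_dna(300), h_dna(300)))
  bw <- list(list(id = "a", forward = TRUE), list(id = "b", forward = TRUE))
  expect_error(merge_walk_sequence(bad, bw, L, FALSE), "overlap mismatch")
})

test_that("two queries claiming one contig via seemingly unique paths both fail", {
  set.seed(37)
  L <- 60L
  S1 <- h_dna(L); S2 <- h_dna(L)
  X <- paste0(S1, h_dna(400)) # X left end shared by both queries' right ends
  Q1 <- paste0(h_dna(400), S1)
  Q2 <- paste0(h_dna(380), S1)
  cs <- contig_set(c("Q1", "Q2", "X"), c(Q1, Q2, X))
  idx <- build_overlap_index(cs, L)
  cov <- c(Q1 = 20, Q2 = 20, X = 40)
  lnk <- linkage_from_pairs(data.frame(a = c("Q1", "Q2"), b = "X",
                                       count = 5L))
  params <- h_params(L)
  res <- lapply(c("Q1", "Q2"), extend_query, contigs = cs, index = idx,
                coverage = cov, linkage = lnk, params = params)
  expect_equal(vapply(res, `[[`, character(1), "category"),
               rep("extended_partial", 2))
  res2 <- resolve_cross_query_conflicts(res, cs)
  expect_equal(vapply(res2, `[[`, character(1), "category"),
               rep("extended_failed", 2))
})

test_that("a query whose two ends extend into near-duplicate contigs fails", {
  set.seed(38)
  L <- 99L
  X <- h_dna(2000)
  # variant with one substitution inside each end window: all four end
  # L-mers distinct, k-mer containment still high
  flip <- function(s, i) {
    b <- substr(s, i, i)
    nb <- setdiff(c("A", "C", "G", "T"), b)[1]
    paste0(substr(s, 1, i - 1), nb, substr(s, i + 1, nchar(s)))
  }
  X2 <- flip(flip(X, 50), 1950)
  Q <- paste0(substr(X2, 2000 - L + 1, 2000), h_dna(600), substr(X, 1, L))
  cs <- contig_set(c("Q", "X", "X2"), c(Q, X, X2))
  idx <- build_overlap_index(cs, L)
  cov <- c(Q = 20, X = 20, X2 = 20)
  lnk <- linkage_from_pairs(data.frame(a = c("Q", "Q"), b = c("X", "X2"),
                                       count = 5L))
  r <- extend_query("Q", cs, idx, cov, lnk, h_params(L))
  expect_equal(r$category, "extended_partial")
  expect_setequal(c(r$left_ids, r$right_ids), c("X", "X2"))
  r2 <- resolve_cross_query_conflicts(list(r), cs)
  expect_equal(r2[[1]]$category, "extended_failed")

  # disjoint walks are unchanged
  fx <- h_chain(2, L = L)
  fidx <- build_overlap_index(fx$contigs, L)
  rd <- extend_query(fx$ids[1], fx$contigs, fidx, fx$coverage, fx$linkage,
                     h_params(L))
  expect_equal(resolve_cross_query_conflicts(list(rd), fx$contigs)[[1]],
               rd)
})

test_that("run_cobra partitions queries, is deterministic, and handles edge inputs", {
  set.seed(39)
  L <- 99L
  fx <- h_chain(3, frag_len = 400, L = L)
  lone <- h_dna(500)
  seqs <- c(fx$seqs, lone = lone)
  asm <- h_write_fasta(seqs)
  qry <- h_write_fasta(seqs[c(1, 4)])
  covp <- tempfile(fileext = ".tsv")
  writeLines(sprintf("%s\t20", names(seqs)), covp)
  res <- run_cobra(asm, qry, covp, fx$linkage, "metaspades", L, 21)
  expect_equal(sum(res$counts), 2)
  expect_equal(unname(res$counts["extended_partial"]), 1)
  expect_equal(unname(res$counts["orphan_end"]), 1)
  # every query in exactly one category
  expect_equal(sort(res$summary$query_id), sort(c(fx$ids[1], "lone")))

  # determinism across FASTA record shuffles
  shuffled <- sample(seqs)
  asm2 <- h_write_fasta(shuffled)
  res2 <- run_cobra(asm2, qry, covp, fx$linkage, "metaspades", L, 21)
  expect_equal(res$summary, res2$summary)

  # empty query set
  empty <- h_write_fasta(character())
  res3 <- run_cobra(asm, empty, covp, fx$linkage, "metaspades", L, 21)
  expect_equal(sum(res3$counts), 0)
  expect_equal(nrow(res3$summary), 0L)

  # query id absent from the assembly
  qbad <- h_write_fasta(c(ghost = h_dna(300)))
  expect_error(run_cobra(asm, qbad, covp, fx$linkage, "metaspades", L, 21),
               "absent")

  # query file == assembly file runs and keeps the partition
  res4 <- run_cobra(asm, asm, covp, fx$linkage, "metaspades", L, 21)
  expect_equal(sum(res4$counts), length(seqs))
})

test_that("canonical_rotation equals the brute-force minimum over all rotations", {
  set.seed(40)
  brute <- function(s) {
    n <- nchar(s)
    dd <- paste0(s, s)
    min(substring(dd, 1:n, (1:n) + n - 1))
  }
  for (i in 1:50) {
    s <- h_dna(sample(1:60, 1))
    expect_equal(canonical_rotation(s),
                 min(brute(s), brute(h_rc(s))))
  }
  # rotation- and strand-invariance
  s <- h_dna(500)
  rot <- paste0(substr(s, 101, 500), substr(s, 1, 100))
  expect_equal(canonical_rotation(rot), canonical_rotation(s))
  expect_equal(canonical_rotation(h_rc(rot)), canonical_rotation(s))
})
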