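test_that("kernel parameterizations derive lambda and beta correctly", {
  uo <- discovery_condition(30, 4, "UO")
  expect_equal(uo$lambda, 3L)   # floor(4/2)+1
  expect_equal(uo$beta, 1L)
  imus <- discovery_condition(30, 2, "IMUS")
  expect_equal(imus$lambda, 2L)
  expect_equal(imus$beta, 1L)   # floor(2/2)
  imus4 <- discovery_condition(16, 4, "IMUS")
  expect_equal(imus4$beta, 2L)
  expect_error(discovery_condition(5, 5, "UO"), "d < l")
  expect_error(discovery_condition(5, 0, "UO"), "d < l")
})

test_that("partition schemes tile the pattern with near-equal parts", {
  expect_equal(make_scheme(discovery_condition(30, 4, "UO"))$length,
               c(10L, 10L, 10L))
  expect_equal(make_scheme(discovery_condition(30, 2, "IMUS"))$length,
               c(15L, 15L))
  expect_equal(make_scheme(discovery_condition(27, 4, "UO"))$length,
               c(9L, 9L, 9L))
  # non-divisible lengths: longer parts first, all differ by <= 1
  sch <- make_scheme(discovery_condition(13, 2, "IMUS"))
  expect_equal(sch$length, c(7L, 6L))
  sch <- make_scheme(discovery_condition(16, 5, "UO"))  # lambda = 3
  expect_equal(sch$length, c(6L, 5L, 5L))
  for (cond in list(discovery_condition(11, 4, "UO"),
                    discovery_condition(9, 7, "IMUS"))) {
    sch <- make_scheme(cond)
    expect_equal(sum(sch$length), cond$l)
    expect_equal(sch$start, cumsum(c(0L, sch$length[-nrow(sch)])))
    expect_lte(diff(range(sch$length)), 1L)
  }
  degenerate <- structure(list(l = 3L, d = 2L, kernel = "UO",
                               lambda = 7L, beta = 1L),
                          class = "discovery_condition")
  expect_error(make_scheme(degenerate), "exceeds pattern length")
})

test_that("neighbor_keys enumerates the hamming ball of a key", {
  expect_identical(neighbor_keys("ACGT", 0), "ACGT")
  # beta = 1: the key plus its 3*alpha single-base permutations
  for (key in c("A", "ACG", "TTTTT", "ACGTACGT")) {
    nb <- neighbor_keys(key, 1)
    expect_equal(length(nb), 3L * nchar(key) + 1L)
    expect_false(any(duplicated(nb)))
    expect_true(all(vapply(nb, hamming, integer(1), b = key) <= 1L))
  }
  # beta = 2 on a 3-mer, against an exhaustive scan of all 64 3-mers
  all3 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 3)), 1,
                paste, collapse = "")
  oracle <- all3[vapply(all3, hamming, integer(1), b = "ACG") <= 2L]
  expect_setequal(neighbor_keys("ACG", 2), oracle)
  expect_equal(length(neighbor_keys("ACG", 2)), 37L)
})

test_that("the index lists every occurrence once per slot, candidates first", {
  db <- toy_db()
  cond <- discovery_condition(5, 1, "IMUS")  # lambda 2, parts 3+2
  occ <- extract_occurrences(db, 5)

  idx_all <- build_index(db, cond, occ)
  sizes <- index_entry_sizes(idx_all)
  expect_true(all(sizes$n_candidates == sizes$n_total))
  expect_equal(sum(sizes$n_total), cond$lambda * nrow(occ))

  idx_none <- build_index(db, cond, occ[0, ])
  expect_true(all(index_entry_sizes(idx_none)$n_candidates == 0L))

  # partial candidate set on a random database: candidate block leads
  db2 <- generate_db(2, 80, seed = 3)
  occ2 <- extract_occurrences(db2, 8)
  cand <- occ2[seq(1, nrow(occ2), by = 3), ]
  cond2 <- discovery_condition(8, 2, "IMUS")
  idx <- build_index(db2, cond2, cand)
  sizes2 <- index_entry_sizes(idx)
  expect_equal(sum(sizes2$n_total), cond2$lambda * nrow(occ2))
  expect_equal(sum(sizes2$n_candidates), cond2$lambda * nrow(cand))
  cand_key <- paste(cand$seq_index, cand$offset)
  for (nm in ls(idx$entries)) {
    e <- get(nm, envir = idx$entries)
    flags <- paste(idx$occ$seq_index[e$occ_idx],
                   idx$occ$offset[e$occ_idx]) %in% cand_key
    expect_equal(sum(flags), e$candidate_end)
    if (e$candidate_end > 0)
      expect_true(all(flags[seq_len(e$candidate_end)]))
  }
  expect_error(build_index(db2, cond2, data.frame(seq_index = 0L, offset = 0L,
                                                  length = 5L)),
               "length")
})

test_that("similar entries are exactly the slot-mates within beta key mismatches", {
  db <- toy_db()
  # IMUS at (5,1): halves of lengths 3+2, so slot-0 keys are 3-mers
  cond <- discovery_condition(5, 1, "IMUS")
  occ <- extract_occurrences(db, 5)
  idx <- build_index(db, cond, occ)
  ents <- similar_entries(idx, "CCC", 0)
  hit_strings <- unlist(lapply(ents, function(e)
    unisig:::occ_strings(db, idx$occ[e$occ_idx, ])))
  expect_true("CCCTA" %in% hit_strings)

  # oracle: filter all entries of a slot by key hamming distance
  db2 <- generate_db(2, 60, seed = 7)
  cond2 <- discovery_condition(6, 2, "IMUS")
  idx2 <- build_index(db2, cond2, extract_occurrences(db2, 6))
  sizes <- index_entry_sizes(idx2)
  for (slot in 0:1) {
    slot_keys <- sizes$key[sizes$slot == slot]
    probe <- slot_keys[1]
    got <- sort(names(similar_entries(idx2, probe, slot)))
    want <- sort(slot_keys[vapply(slot_keys, hamming, integer(1),
                                  b = probe) <= cond2$beta])
    expect_equal(got, want)
  }
  # beta = 0 keeps at most the key's own entry
  cond0 <- discovery_condition(6, 1, "IMUS")  # beta = floor(1/2) = 0
  idx0 <- build_index(db2, cond0, extract_occurrences(db2, 6))
  k0 <- index_entry_sizes(idx0)$key[1]
  expect_equal(names(similar_entries(idx0, k0, 0)), k0)
})

test_that("pigeonhole soundness: a near pair always shares a near key in some slot", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (kern in c("UO", "IMUS")) {
    for (case in 1:40) {
      l <- sample(4:10, 1)
      d <- sample(seq_len(min(4, l - 1)), 1)
      cond <- discovery_condition(l, d, kern)
      if (cond$lambda > l) next
      sch <- make_scheme(cond)
      p <- sample(bases, l, replace = TRUE)
      q <- p
      flips <- sample(l, sample(0:d, 1))
      for (f in flips) q[f] <- sample(setdiff(bases, p[f]), 1)
      slot_ok <- vapply(seq_len(nrow(sch)), function(s) {
        iv <- sch$start[s] + seq_len(sch$length[s])
        sum(p[iv] != q[iv]) <= cond$beta
      }, logical(1))
      expect_true(any(slot_ok))
    }
  }
})

test_that("index completeness: near occurrence pairs meet in a similar entry pair", {
  db <- generate_db(2, 40, seed = 13)
  cond <- discovery_condition(6, 2, "UO")
  occ <- extract_occurrences(db, 6)
  idx <- build_index(db, cond, occ)
  sch <- idx$scheme
  strs <- unisig:::occ_strings(db, idx$occ)
  n <- nrow(idx$occ)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (hamming(strs[i], strs[j]) > cond$d) next
    keyed <- vapply(seq_len(nrow(sch)), function(s) {
      ki <- substr(strs[i], sch$start[s] + 1, sch$start[s] + sch$length[s])
      kj <- substr(strs[j], sch$start[s] + 1, sch$start[s] + sch$length[s])
      hamming(ki, kj) <= cond$beta
    }, logical(1))
    expect_true(any(keyed))
  }
})
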