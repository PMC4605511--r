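# Palindrome detection, exclusion filters, tallies and control sampling.

test_that("is_palindrome is character-exact and 'X' never matches itself", {
  expect_true(is_palindrome("RALAR"))
  expect_true(is_palindrome("VGFFGV"))        # even length
  expect_true(is_palindrome("GDNPRPNDG"))
  expect_false(is_palindrome("AAIAC"))
  expect_false(is_palindrome("AXA"))
  expect_false(is_palindrome("XXXXX"))
  expect_error(is_palindrome(""), "empty")
})

test_that("enumerate_palindromes reports every window once, sorted", {
  h <- enumerate_palindromes(make_chain("FAFAFA"), scan_config())
  expect_equal(h$sequence, c("FAFAF", "AFAFA"))
  expect_equal(h$start_index, c(0L, 1L))

  h <- enumerate_palindromes(make_chain("AEQKAKQEA"), scan_config())
  expect_equal(h$sequence, c("AEQKAKQEA", "EQKAKQE", "QKAKQ"))
  expect_equal(h$start_index, c(0L, 1L, 2L))

  expect_equal(nrow(enumerate_palindromes(make_chain("AAAA"),
                                          scan_config())), 0L)
})

test_that("author numbering on hits matches the 1-based inclusive convention", {
  ch <- make_chain("LMQKAKQGV", resno = 461:469)
  h <- enumerate_palindromes(ch, scan_config())
  expect_equal(h$sequence, "QKAKQ")
  expect_equal(c(h$start_resno, h$end_resno), c(463L, 467L))
})

test_that("filter_hits removes CARPs, incomplete windows and duplicates", {
  ch <- make_chain("GGAAAAAGG")
  h <- enumerate_palindromes(ch, scan_config())
  expect_true("AAAAA" %in% h$sequence)
  f <- filter_hits(h, ch, scan_config())
  expect_false("AAAAA" %in% f$sequence)       # CARP gone
  expect_true("GAAAAAG" %in% f$sequence)      # two-letter windows kept
  excl <- attr(f, "excluded")
  expect_true(all(excl$reason[excl$sequence == "AAAAA"] == "carp"))

  ch2 <- make_chain("QKAKQ")
  f2 <- filter_hits(enumerate_palindromes(ch2, scan_config()), ch2,
                    scan_config())
  expect_equal(f2$sequence, "QKAKQ")          # passes all filters

  ch3 <- make_chain("DNYND", complete = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  f3 <- filter_hits(enumerate_palindromes(ch3, scan_config()), ch3,
                    scan_config())
  expect_equal(nrow(f3), 0L)
  expect_equal(attr(f3, "excluded")$reason, "incomplete")

  bad <- enumerate_palindromes(make_chain("AEQKAKQEA"), scan_config())
  expect_error(filter_hits(bad, make_chain("AAA"), scan_config()),
               "outside")
})

test_that("every emitted hit is a palindrome and CARP-free after filtering", {
  set.seed(42)
  for (k in 1:50) {
    ch <- make_chain(random_aa_string(60))
    f <- filter_hits(enumerate_palindromes(ch, scan_config()), ch,
                     scan_config())
    if (!nrow(f)) next
    expect_true(all(is_palindrome(f$sequence)))
    expect_true(all(vapply(strsplit(f$sequence, ""), function(x)
      length(unique(x)) >= 2, logical(1))))
    expect_equal(f$length, f$end_index - f$start_index)
  }
})

test_that("enumeration is monotone in min_len/max_len and closed under centers", {
  set.seed(7)
  for (k in 1:25) {
    ch <- make_chain(random_aa_string(50))
    h5 <- enumerate_palindromes(ch, scan_config(min_len = 5))
    h3 <- enumerate_palindromes(ch, scan_config(min_len = 3))
    h57 <- enumerate_palindromes(ch, scan_config(min_len = 5, max_len = 7))
    expect_gte(nrow(h3), nrow(h5))
    expect_lte(nrow(h57), nrow(h5))
    # odd-length hits of length >= 7 contain a co-centered L-2 hit
    long <- h3[h3$length >= 7 & h3$length %% 2 == 1, , drop = FALSE]
    for (i in seq_len(nrow(long))) {
      expect_true(any(h3$start_index == long$start_index[i] + 1L &
                        h3$length == long$length[i] - 2L))
    }
  }
})

test_that("enumeration agrees with the literal probe/target oracle", {
  set.seed(11)
  for (k in 1:150) {
    s <- random_aa_string(sample(10:60, 1))
    ch <- make_chain(s)
    mine <- filter_hits(enumerate_palindromes(ch, scan_config()), ch,
                        scan_config())
    ref <- oracle_filter(oracle_probe_target(s))
    expect_equal(mine[, c("start_index", "length", "sequence")], ref,
                 ignore_attr = TRUE)
  }
})

test_that("unique_sequences counts distinct strings once with multiplicity", {
  hits <- rbind(
    enumerate_palindromes(make_chain("AAIAA", pdb_id = "1EKQ"),
                          scan_config()),
    enumerate_palindromes(make_chain("AAIAA", pdb_id = "2RFR"),
                          scan_config()))
  u <- unique_sequences(hits)
  expect_equal(u$by_length$n_unique, 1L)
  expect_equal(u$by_length$n_hits, 2L)
  expect_equal(u$multiplicity$n_occurrences, 2L)

  u0 <- unique_sequences(hits[0, ])
  expect_equal(nrow(u0$by_length), 0L)

  h2 <- enumerate_palindromes(make_chain("AEQKAKQEA"), scan_config(max_len = 9))
  u2 <- unique_sequences(h2[h2$length %in% c(5, 9), ])
  expect_equal(u2$by_length$length, c(5L, 9L))
  expect_equal(u2$by_length$n_unique, c(1L, 1L))
})

test_that("control windows match hit lengths, avoid palindromes, and are seeded", {
  set.seed(3)
  chains <- lapply(1:5, function(i)
    make_chain(paste0(random_aa_string(40), "QKAKQ", random_aa_string(20),
                      "VGFFGV", random_aa_string(15)),
               pdb_id = paste0("SYN", i)))
  hits <- do.call(rbind, lapply(chains, function(ch)
    filter_hits(enumerate_palindromes(ch, scan_config()), ch,
                scan_config())))
  ctrl <- sample_control_windows(chains, hits, scan_config(seed = 5))
  expect_equal(nrow(ctrl), nrow(hits))
  expect_equal(table(ctrl$length), table(hits$length))
  expect_false(any(is_palindrome(ctrl$sequence)))
  expect_false(any(paste(ctrl$pdb_id, ctrl$chain_id, ctrl$start_index,
                         ctrl$length) %in%
                     paste(hits$pdb_id, hits$chain_id, hits$start_index,
                           hits$length)))
  ctrl2 <- sample_control_windows(chains, hits, scan_config(seed = 5))
  expect_identical(ctrl, ctrl2)
  ctrl3 <- sample_control_windows(chains, hits, scan_config(seed = 6))
  expect_false(identical(ctrl, ctrl3))
})

test_that("control sampling errors when no valid placement exists", {
  ch <- make_chain("ALALA")   # every length-5 window is palindromic
  hits <- enumerate_palindromes(ch, scan_config())
  expect_error(sample_control_windows(list(ch), hits, scan_config()),
               "too small")
})

test_that("maximal-only mode drops contained sub-palindromes", {
  h <- enumerate_palindromes(make_chain("AEQKAKQEA"),
                             scan_config(maximal_only = TRUE))
  expect_equal(h$sequence, "AEQKAKQEA")
})

test_that("FASTA scanning finds the same hits as direct enumeration", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqinr::write.fasta(list("LMQKAKQGV", "FAFAFA"), names = c("s1", "s2"),
                      file.out = path, nbchar = 60)
  h <- scan_fasta(path)
  expect_equal(sort(h$sequence), c("AFAFA", "FAFAF", "QKAKQ"))
})
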