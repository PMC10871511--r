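neutral_counts <- function(f) unclass(f$composition)[1:5]

test_that("backbone cleavage conserves atoms and honors its site rules", {
  rt <- residue_table()
  set.seed(11)
  seqs <- c("G", "AA", "QFA", "WHA", "SEQA",
            replicate(5, paste(sample(rt$code, sample(2:4, 1),
                                      replace = TRUE), collapse = "")))
  for (s in seqs) {
    p <- assemble_peptide(s)
    n <- nchar(s)
    a <- cleave_type_a(p)
    b <- cleave_type_b(p)
    cc <- cleave_type_c(p)
    expect_length(a, 2 * n)
    expect_length(b, if (n >= 2) 2 * (n - 1) else 0)
    n_arom <- sum(strsplit(s, "")[[1]] %in% c("F", "W", "Y"))
    expect_length(cc, 2 * n_arom)
    # complementary pieces sum to the parent, exactly
    for (pieces in list(a, b, cc)) {
      for (k in seq_len(length(pieces) / 2)) {
        tot <- neutral_counts(pieces[[2 * k - 1]]) +
          neutral_counts(pieces[[2 * k]])
        expect_identical(tot, neutral_counts(p), info = s)
      }
    }
  }
  # single free amino acid: Type A N-side piece is the M-45 loss
  g <- cleave_type_a(assemble_peptide("G"))
  expect_identical(neutral_counts(g[[1]]),
                   c(C = 1L, H = 4L, N = 1L, O = 0L, S = 0L))
  expect_equal(round(monoisotopic_mass(g[[1]]$composition)), 30)
  # Ala-Ala acylium-type piece from its single peptide bond
  b <- cleave_type_b(assemble_peptide("AA"))
  expect_equal(round(monoisotopic_mass(b[[1]]$composition), 2), 72.04)
  expect_length(cleave_type_b(assemble_peptide("A")), 0)
  expect_length(cleave_type_c(assemble_peptide("QKA")), 0)
})

test_that("C-terminal degradations respect eligibility and alkene pairing", {
  cat_ <- builtin_catalogue()
  ala <- assemble_peptide("A")
  kids <- apply_cterm_events(ala, cat_)
  expect_length(kids, 3)
  d <- vapply(kids, function(f) {
    monoisotopic_mass(ala$composition) - monoisotopic_mass(f$composition)
  }, 0)
  expect_equal(round(d), c(45, 17, 18))
  expect_false(any(vapply(kids, `[[`, TRUE, "has_cterm")))
  # ineligible parent: nothing to do
  ineligible <- kids[[1]]
  expect_length(apply_cterm_events(ineligible, cat_), 0)
  # Ile pairs each carboxyl event with alkene formation; whole + alkene
  # is the observed M-46 and consumes Ile's side-event slot
  ile <- assemble_peptide("I")
  ik <- apply_cterm_events(ile, cat_)
  expect_length(ik, 6)
  d46 <- vapply(ik, function(f) {
    monoisotopic_mass(ile$composition) - monoisotopic_mass(f$composition)
  }, 0)
  expect_true(any(round(d46) == 46))
  paired <- ik[vapply(ik, function(f) any(grepl("alkene", f$path)), TRUE)]
  expect_true(all(vapply(paired, function(f) f$side_used[[1]], TRUE)))
})

test_that("side events apply at most once per residue and charged ions are terminal", {
  cat_ <- builtin_catalogue()
  q <- assemble_peptide("Q")
  kids <- apply_side_events(q, cat_)
  expect_length(kids, 2)   # ammonia loss, generic side-chain loss
  for (k in kids) {
    expect_true(k$side_used[[1]])
    expect_length(apply_side_events(k, cat_), 0)   # slot consumed
  }
  # charged children carry the payload ion itself and no residues
  f <- assemble_peptide("F")
  ions <- Filter(function(k) length(k$codes) == 0,
                 apply_side_events(f, cat_))
  expect_length(ions, 2)
  expect_equal(round(monoisotopic_mass(ions[[1]]$composition), 1), 91.1)
  expect_length(apply_side_events(ions[[1]], cat_), 0)
})

test_that("the doubly degraded glutamine species is enumerated", {
  # combined C-terminal carboxyl loss and side-chain ammonia loss
  ps <- enumerate_fragments("Q")
  target <- comp_subtract(comp_subtract(assemble_peptide("Q")$composition,
                                        composition(1, 1, 0, 2)),
                          composition(h_count = 3, n_count = 1))
  keys <- engine_keys(ps)
  expect_true(oracle_key(unclass(target)) %in% keys)
  # the common 74 m/z backbone cation from generic side-chain loss
  expect_true(any(round(ps$mz) == 74))
})

test_that("full enumeration matches the brute-force oracle for all single amino acids", {
  rt <- residue_table()
  for (code in rt$code) {
    ps <- enumerate_fragments(code)
    expect_identical(engine_keys(ps), oracle_single_aa(code), info = code)
    expect_true(all(vapply(ps$fragments,
                           function(f) f$composition[["z"]] == 1L, TRUE)))
  }
})

test_that("QFA enumerates to the calibrated fingerprint", {
  ps <- enumerate_fragments("QFA")
  expect_length(ps$fragments, 55)
  # includes the intact molecular ion
  intact <- Filter(function(f) length(f$path) == 0, ps$fragments)
  expect_length(intact, 1)
  expect_equal(round(monoisotopic_mass(intact[[1]]$composition), 2),
               364.17)
  # no negative atom counts anywhere
  for (f in ps$fragments) expect_true(all(neutral_counts(f) >= 0))
})

test_that("deduplication is idempotent and filters negative counts", {
  ps <- enumerate_fragments("QFA")
  once <- dedupe_and_filter(ps$fragments)
  twice <- dedupe_and_filter(once)
  expect_identical(lapply(twice, `[[`, "composition"),
                   lapply(once, `[[`, "composition"))
  expect_identical(vapply(twice, function(f) f$n_routes, 0L),
                   vapply(once, function(f) f$n_routes, 0L))
  neg <- assemble_peptide("G")
  neg$composition <- comp_subtract(neg$composition, composition(0, 0, 0, 9))
  expect_length(dedupe_and_filter(list(neg)), 0)
})

test_that("enumeration is deterministic and monotone in the catalogue", {
  a <- as.data.frame(enumerate_fragments("WHA"))
  b <- as.data.frame(enumerate_fragments("WHA"))
  expect_identical(a, b)
  # adding a mechanism never removes a predicted fragment
  f <- withr::local_tempfile(fileext = ".txt")
  write_mechanisms(builtin_catalogue(), f)
  cat(" A | side methyl radical loss | relative | 1,3,0,0,0,0\n",
      file = f, append = TRUE)
  wider <- read_mechanisms(f)
  base_keys <- engine_keys(enumerate_fragments("QFA"))
  wide_keys <- engine_keys(enumerate_fragments("QFA", wider))
  expect_true(all(base_keys %in% wide_keys))
  expect_gt(length(wide_keys), length(base_keys))
})

test_that("non-relative ion m/z is invariant across sequence contexts", {
  for (s in c("AFA", "WFA", "QFA")) {
    ps <- enumerate_fragments(s)
    hit <- abs(ps$mz - 91.0548) < 1e-4
    expect_true(any(hit), info = s)
    ion <- ps$fragments[hit][[1]]
    expect_identical(neutral_counts(ion),
                     c(C = 7L, H = 7L, N = 0L, O = 0L, S = 0L), info = s)
  }
})

test_that("prediction output writes and reports coherently", {
  ps <- enumerate_fragments("QFA")
  df <- as.data.frame(ps)
  expect_identical(nrow(df), 55L)
  expect_false(is.unsorted(df$mz))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(ps, f)
  lines <- readLines(f)
  expect_match(lines[1], "sequence: QFA")
  got <- utils::read.delim(f, comment.char = "#")
  expect_identical(nrow(got), 55L)
  expect_equal(got$mz, round(ps$mz[order(ps$mz)], 4))
})
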