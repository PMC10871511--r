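test_that("built-in catalogue carries the confirmed events", {
  cat_ <- builtin_catalogue()

  pick <- function(label, res) {
    hit <- cat_[cat_$label == label & cat_$residues == res, ]
    expect_equal(nrow(hit), 1L, info = paste(label, res))
    hit
  }
  # beta-elimination of Ser loses water (nominal M-18)
  expect_identical(pick("side beta elimination", "S")$payload[[1]],
                   composition(h_count = 2, o_count = 1))
  expect_equal(nominal_delta(pick("side beta elimination", "S")), -18L)
  # Met methylene sub-fragment ion at 61.0
  m <- pick("charged side chain methylene sub frag loss", "M")
  expect_identical(m$kind, "charged")
  expect_equal(round(monoisotopic_mass(m$payload[[1]]), 1), 61.0)
  # glycine has no residue-scoped mechanisms at all
  expect_equal(sum(cat_$residues == "G"), 0L)
  # Ala/Gly/Pro/Tyr are outside the generic lost-side-chain list
  scl <- cat_$residues[cat_$label == "side chain loss"]
  expect_setequal(scl, strsplit("CDEFHIKLMNQRSTVW", "")[[1]])

  # reserved-word and payload-charge invariants
  expect_false(any(grepl("type", cat_$label)))
  for (i in seq_len(nrow(cat_))) {
    z <- cat_$payload[[i]][["z"]]
    expect_identical(z, if (cat_$kind[[i]] == "charged") 1L else 0L)
  }
  # applying all of a residue's relative events never removes more atoms
  # of an element than the free residue contains (each event singly,
  # since only one side event per residue is legal)
  rt <- residue_table()
  for (i in which(cat_$kind == "relative" & cat_$residues != "CTERM")) {
    free <- rt$free[[match(cat_$residues[[i]], rt$code)]]
    left <- comp_subtract(free, cat_$payload[[i]])
    expect_true(all(unclass(left)[1:5] >= 0L),
                info = paste(cat_$label[[i]], cat_$residues[[i]]))
  }
})

test_that("nominal deltas reproduce the tabulated M-x integers", {
  cat_ <- builtin_catalogue()
  delta <- function(label, res) {
    nominal_delta(cat_[cat_$label == label & cat_$residues == res, ])
  }
  expect_equal(delta("side ammonia loss", "Q"), -17L)
  expect_equal(delta("side beta elimination", "T"), -18L)
  expect_equal(delta("side beta elimination", "C"), -34L)
  expect_equal(delta("side carboxylic acid whole", "D"), -45L)
  expect_equal(delta("side carboxylic acid partial radical", "E"), -17L)
  expect_equal(delta("side carboxylic acid partial", "E"), -18L)
  expect_equal(delta("side partial chain loss", "M"), -61L)
  expect_equal(delta("side chain cyclization", "K"), -17L)
  expect_equal(delta("side partial guanidino loss", "R"), -42L)
  expect_equal(delta("side guanidino loss alkene", "R"), -60L)
  expect_equal(delta("carboxylic acid whole", "CTERM"), -45L)
  expect_equal(delta("carboxylic acid partial radical", "CTERM"), -17L)
  expect_equal(delta("carboxylic acid partial", "CTERM"), -18L)
  # C-terminus + alkene combine to the observed M-46
  expect_equal(delta("carboxylic acid whole", "CTERM") +
                 delta("alkene formation", "I"), -46L)
  expect_error(nominal_delta(cat_[cat_$kind == "charged", ][1, ]),
               "relative")
})

test_that("definition-file dialect round-trips and enforces flag words", {
  cat_ <- builtin_catalogue()
  f <- withr::local_tempfile(fileext = ".txt")
  write_mechanisms(cat_, f)
  back <- read_mechanisms(f)
  expect_identical(as.data.frame(cat_[, c(1:4)]),
                   as.data.frame(back[, c(1:4)]))
  expect_identical(cat_$payload, back$payload)
  # the shipped default file reproduces the built-in catalogue exactly
  shipped <- read_mechanisms(system.file("extdata", "mechanisms.txt",
                                         package = "eifrag"))
  expect_identical(cat_$payload, shipped$payload)
  expect_identical(cat_$label, shipped$label)
  expect_identical(cat_$residues, shipped$residues)

  parse1 <- function(line) {
    g <- withr::local_tempfile(fileext = ".txt")
    writeLines(line, g)
    read_mechanisms(g)
  }
  one <- parse1("Q | side ammonia loss | relative | 0,3,1,0,0,0")
  expect_identical(one$residues, "Q")
  expect_identical(one$scope, "side")
  expect_identical(one$payload[[1]], composition(h_count = 3, n_count = 1))
  ion <- parse1("F | charged side chain loss | charged | 7,7,0,0,0,1")
  expect_identical(ion$kind, "charged")
  expect_identical(ion$payload[[1]][["z"]], 1L)
  # multi-residue records expand; scope falls out of the flag words
  multi <- parse1("KPI | alkene formation | relative | 0,1,0,0,0,0")
  expect_identical(multi$residues, c("K", "P", "I"))
  expect_true(all(multi$scope == "cterm-paired"))

  expect_error(parse1("Q | type weird loss | relative | 0,3,1,0,0,0"),
               "reserved")
  expect_error(parse1("Q | side x | relative | 0,3,1,0,0"), "line 1")
  expect_error(parse1("Z | side x | relative | 0,3,1,0,0,0"), "unknown")
  expect_error(parse1("Q | side x | maybe | 0,3,1,0,0,0"), "kind")
  expect_error(parse1("Q | side x | charged | 0,3,1,0,0,0"), "charge")
})
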