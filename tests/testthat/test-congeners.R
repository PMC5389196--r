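# Symmetry group, canonicalization, enumeration, naming and SMILES export.

test_that("the skeleton symmetry group has the required structure", {
  g <- dioxin_symmetry_group()
  expect_length(g, 4L)
  expect_identical(g$identity, 1:8)
  # every non-identity element is an involution with no fixed position
  for (nm in setdiff(names(g), "identity")) {
    p <- g[[nm]]
    expect_identical(p[p], 1:8)
    expect_true(all(p != 1:8))
  }
  # closed under composition: composing the two mirrors gives the rotation
  expect_identical(g$mirror_x[g$mirror_y], g$rotation_2)
  comp <- vapply(g, function(a) {
    vapply(g, function(b) paste(a[b], collapse = ","), character(1))
  }, character(4))
  expect_true(all(comp %in% vapply(g, paste, character(1), collapse = ",")))
})

test_that("canonicalize is idempotent and constant on orbits", {
  g <- dioxin_symmetry_group()
  set.seed(101)
  for (rep in 1:50) {
    s <- random_state()
    can <- canonicalize(s, g)
    expect_identical(canonicalize(can, g), can)
    expect_identical(can, oracle_canonical(s, g))
    for (img in oracle_orbit(s, g)) {
      expect_identical(canonicalize(img, g), can)
    }
  }
  # 2,3,7,8-tetra-Cl is a fixed point of the whole group
  tcdd <- c("H", "Cl", "Cl", "H", "H", "Cl", "Cl", "H")
  expect_identical(canonicalize(tcdd), tcdd)
  # 1-chloro and 9-chloro substitution patterns share a canonical form
  expect_identical(canonicalize(c("Cl", rep("H", 7))),
                   canonicalize(c(rep("H", 7), "Cl")))
  expect_error(canonicalize(c("H", "H")), "length 8")
  expect_error(canonicalize(c(rep("H", 7), "F")), "invalid")
})

test_that("enumeration counts match brute force and Burnside's lemma", {
  full <- enumerate_congeners()
  expect_equal(nrow(full), 1701L)
  expect_equal(nrow(full), (3^8 + 3 * 3^4) / 4)  # Burnside, k = 3
  hcl <- enumerate_congeners(alphabet = c("H", "Cl"))
  expect_equal(nrow(hcl), 76L)
  expect_equal(nrow(hcl), (2^8 + 3 * 2^4) / 4)   # Burnside, k = 2
  # brute force: canonicalize every raw pattern and count distinct forms
  raw <- oracle_all_states(c("H", "Cl"))
  cans <- unique(vapply(raw, function(s) {
    paste(canonicalize(s), collapse = ".")
  }, character(1)))
  expect_equal(length(cans), 76L)
  expect_setequal(cans, apply(hcl, 1L, paste, collapse = "."))
  # parent included, rows are canonical and unique, order lexicographic
  expect_identical(full[1L, ], c(pos1 = "H", pos2 = "H", pos3 = "H",
                                 pos4 = "H", pos6 = "H", pos7 = "H",
                                 pos8 = "H", pos9 = "H"))
  keys <- apply(full, 1L, function(s) {
    paste(sprintf("%d", match(s, substituent_alphabet())), collapse = "")
  })
  expect_false(is.unsorted(keys))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("mono-substitution yields one orbit per position class", {
  one_cl <- enumerate_congeners(alphabet = c("H", "Cl"))
  counts <- rowSums(one_cl == "Cl")
  expect_equal(sum(counts == 1L), 2L)  # lateral {2,3,7,8} and axial {1,4,6,9}
})

test_that("orbit sizes sum to the raw pattern count", {
  g <- dioxin_symmetry_group()
  full <- enumerate_congeners()
  sizes <- vapply(seq_len(nrow(full)), function(i) {
    nrow(symmetry_orbit(full[i, ], g))
  }, numeric(1))
  expect_equal(sum(sizes), 3^8)
  expect_true(all(sizes %in% c(1, 2, 4)))
})

test_that("congener naming follows IUPAC conventions and is injective", {
  expect_identical(congener_name(c("H", "Cl", "Cl", "H", "H", "Cl", "Cl", "H")),
                   "2,3,7,8-tetrachlorodibenzo-p-dioxin")
  expect_identical(congener_name(rep("Cl", 8)),
                   "1,2,3,4,6,7,8,9-octachlorodibenzo-p-dioxin")
  expect_identical(congener_name(rep("H", 8)), "dibenzo-p-dioxin")
  expect_identical(congener_name(c("Br", "Cl", rep("H", 6))),
                   "1-bromo-2-chlorodibenzo-p-dioxin")
  # lowest-locant renumbering: the canonical tuple of the 1,2,3,7,8 orbit
  # stores halogens at high positions, but the name renumbers
  s <- rep("H", 8)
  s[c(1, 2, 3, 6, 7)] <- "Cl"  # labels 1,2,3,7,8
  expect_identical(congener_name(canonicalize(s)),
                   "1,2,3,7,8-pentachlorodibenzo-p-dioxin")
  tab <- congener_table()
  expect_equal(anyDuplicated(tab$name), 0L)
})

test_that("lateral substitution flag follows the 2,3,7,8 definition", {
  expect_true(is_laterally_substituted(c("H", "Cl", "Cl", "H", "H", "Cl", "Cl", "H")))
  expect_false(is_laterally_substituted(c("Cl", "H", "H", "Cl", "Cl", "H", "H", "Cl")))
  expect_true(is_laterally_substituted(rep("Br", 8)))
})

test_that("SMILES strings encode the correct molecular graph", {
  parent <- to_smiles(rep("H", 8))
  expect_identical(parent, "c1cccc2Oc3ccccc3Oc12")
  tcdd <- to_smiles(c("H", "Cl", "Cl", "H", "H", "Cl", "Cl", "H"))
  expect_identical(tcdd, "c1c(Cl)c(Cl)cc2Oc3cc(Cl)c(Cl)cc3Oc12")
  # orbit members give the same canonical molecular graph (OpenBabel oracle)
  canon <- function(smi) {
    sub("\\s+$", "", ChemmineOB::convertFormat("SMI", "CAN", smi))
  }
  expect_identical(canon(parent), canon("O1c2ccccc2Oc2ccccc21"))
  g <- dioxin_symmetry_group()
  set.seed(202)
  for (rep in 1:5) {
    s <- random_state()
    smis <- vapply(oracle_orbit(s, g), to_smiles, character(1))
    expect_length(unique(vapply(smis, canon, character(1))), 1L)
  }
})

test_that("the congener table carries consistent bookkeeping columns", {
  tab <- congener_table(alphabet = c("H", "Cl"))
  expect_equal(nrow(tab), 76L)
  states <- congener_states(tab)
  expect_equal(tab$n_H, rowSums(states == "H"))
  expect_equal(tab$n_Cl + tab$n_Br + tab$n_H, rep(8, nrow(tab)))
  expect_equal(tab$lateral_flag,
               apply(states, 1L, is_laterally_substituted))
  path <- tempfile(fileext = ".csv")
  write_congener_table(tab, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$name, tab$name)
})
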