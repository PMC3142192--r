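toy <- toy_engine()

test_that("toy duplex energies match hand-derived values and the sentinel", {
  expect_equal(duplex_energy(toy, "GGG", "CCC")$energy, -9)
  d <- duplex_energy(toy, "GAG", "CUC")
  expect_equal(d$energy, -8)
  expect_equal(d$a_pos, 1:3)
  expect_equal(d$b_pos, 3:1)
  s <- duplex_energy(toy, "AAAA", "AAAA")
  expect_true(is.na(s$energy))
  expect_length(s$a_pos, 0)
})

test_that("toy duplex equals the naive matching oracle on random pairs", {
  set.seed(101)
  for (rep in 1:80) {
    n <- sample(3:12, 1); m <- sample(3:12, 1)
    a <- rand_rna(n); b <- rand_rna(m)
    d <- duplex_energy(toy, a, b)
    got <- if (is.na(d$energy)) 0 else -d$energy
    expect_equal(got, oracle_duplex_best(a, b),
                 info = paste(a, b))
    # returned pairing must be antiparallel and achieve the energy
    if (!is.na(d$energy)) {
      expect_true(all(diff(d$a_pos) > 0))
      expect_true(all(diff(d$b_pos) < 0))
      av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
      expect_equal(-sum(mapply(function(i, j) toy_ps(av[i], bv[j]),
                               d$a_pos, d$b_pos)), d$energy)
    }
  }
})

test_that("toy ensemble free energy equals structure enumeration", {
  expect_equal(ensemble_energy(toy, strrep("A", 15)), 0)
  set.seed(7)
  for (rep in 1:25) {
    s <- rand_rna(sample(6:16, 1))
    expect_equal(ensemble_energy(toy, s), oracle_ensemble_energy(s),
                 tolerance = 1e-9, info = s)
    r1 <- sample(nchar(s) - 2, 1); region <- c(r1, min(nchar(s), r1 + 3))
    blocked <- rep(FALSE, nchar(s)); blocked[region[1]:region[2]] <- TRUE
    expect_equal(ensemble_energy(toy, s, region),
                 oracle_ensemble_energy(s, blocked),
                 tolerance = 1e-9, info = s)
  }
})

test_that("constraining a region never lowers the ensemble free energy", {
  set.seed(8)
  for (rep in 1:40) {
    s <- rand_rna(sample(8:30, 1))
    r1 <- sample(nchar(s) - 3, 1); region <- c(r1, r1 + 3)
    expect_gte(ensemble_energy(toy, s, region), ensemble_energy(toy, s))
  }
  # vacuous constraint: sequence with no possible structure
  s <- strrep("A", 14)
  expect_equal(ensemble_energy(toy, s, c(3, 6)), ensemble_energy(toy, s))
})

test_that("opening energies are non-negative and flank policies behave", {
  expect_equal(open_energy(toy, strrep("A", 30), c(5, 10), "full_length"), 0)
  set.seed(9)
  for (rep in 1:30) {
    s <- rand_rna(sample(10:40, 1))
    r1 <- sample(nchar(s) - 4, 1); region <- c(r1, r1 + 4)
    expect_gte(open_energy(toy, s, region, "full_length"), 0)
    expect_gte(open_energy(toy, s, region, "flank_100", flank = 5L), 0)
  }
  expect_error(open_energy(toy, "ACGU", c(2, 9)), "out of bounds")
})

test_that("engines are deterministic", {
  s <- "GGGCAAAAGCCCAUGGGC"
  expect_identical(ensemble_energy(toy, s), ensemble_energy(toy, s))
  expect_identical(duplex_energy(toy, s, s), duplex_energy(toy, s, s))
})

test_that("energy bundles sum hybridization and opening terms", {
  b <- energy_bundle(-10, 3, 2)
  expect_equal(b$ddg, -5)
  expect_true(b$interacting)
  expect_equal(energy_bundle(-10, 0, 0)$ddg, -10)
  nb <- energy_bundle(NA_real_, 0, 0)
  expect_false(nb$interacting)
  expect_true(is.na(nb$ddg))
  expect_error(energy_bundle(-10, -1, 0))
})

test_that("the ViennaRNA adapter reproduces the engine contract", {
  vienna <- vienna_engine()
  d <- duplex_energy(vienna, "GGGGG", "CCCCC")
  expect_lt(d$energy, -5)
  expect_equal(d$a_pos, 1:5)
  expect_equal(d$b_pos, 5:1)
  expect_true(is.na(duplex_energy(vienna, "AAAA", "AAAA")$energy))
  s <- "GGGCAAAAGCCCAUGGGC"
  expect_lt(ensemble_energy(vienna, s), 0)
  expect_gte(ensemble_energy(vienna, s, c(1, 4)), ensemble_energy(vienna, s))
  expect_gte(open_energy(vienna, s, c(1, 4), "full_length"), 0)
  expect_identical(ensemble_energy(vienna, s), ensemble_energy(vienna, s))
  st <- cofold_constrained(vienna, "GGGGGAAAA", "UUUUCCCCC", cbind(1:5, 9:5))
  expect_true(cofold_satisfies(st, cbind(1:5, 9:5), 9))
})
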