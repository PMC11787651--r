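test_that("modification deltas match their elemental compositions", {
  # reference values computed independently from IUPAC isotope masses
  expect_equal(round(modification_delta("me3"), 3), 42.047)
  expect_equal(round(modification_delta("ac"), 3), 42.011)
  expect_equal(round(modification_delta("prop"), 3), 56.026)
  expect_equal(modification_delta("me2"), 2 * modification_delta("me1"))
  # pseudo-isobaric trimethyl/acetyl gap
  gap <- modification_delta("me3") - modification_delta("ac")
  expect_lt(abs(gap - 0.036), 0.001)
  # delta equals the monoisotopic mass of the registered composition
  reg <- default_modifications()
  expect_equal(reg$delta,
               vapply(reg$formula, formula_mass, numeric(1)),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(modification_delta("nosuchmod"), "unknown")
})

test_that("modification registry round-trips through a config file", {
  cfg <- tempfile(fileext = ".txt")
  writeLines(c("# name, targets, formula",
               "ac,K,C2H2O", "gly\tK\tC2H2O2"), cfg)
  reg <- read_modifications(cfg)
  expect_equal(reg$name, c("ac", "gly"))
  expect_equal(modification_delta("gly", reg), formula_mass("C2H2O2"))
  writeLines(c("ac,K,C2H2O", "ac,K,C2H2O"), cfg)
  expect_error(read_modifications(cfg), "duplicate")
})

test_that("monoisotopic masses agree with independent reference values", {
  # frozen values computed with an independent mass calculator (pyteomics)
  expect_equal(monoisotopic_mass("G"), 75.03203, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("GKGGKGLGKGGAKR"), 1269.76295,
               tolerance = 1e-4)
  deriv <- apply_propionylation(peptide_form("GKGGKGLGKGGAKR"))
  expect_equal(monoisotopic_mass(deriv), 1549.89403, tolerance = 1e-4)
  expect_error(peptide_form("GAXR"), "unknown residue")
})

test_that("propionylation targets the N-terminus and eligible lysines", {
  un <- apply_propionylation(peptide_form("GKGGKGLGKGGAKR"))
  expect_equal(sum(un$placements == "prop"), 5) # N-term + 4 K
  k8 <- apply_propionylation(
    peptide_form("GKGGKGLGKGGAKR", c("5" = "ac"), protein = "H4",
                 start = 4))
  expect_equal(sum(k8$placements == "prop"), 4) # one K blocked by ac
  nok <- apply_propionylation(peptide_form("GAGR"))
  expect_equal(sum(nok$placements == "prop"), 1) # N-term only
  # monomethyl lysine carries both me1 and prop
  me1 <- apply_propionylation(peptide_form("GKGR", c("2" = "me1")))
  expect_equal(sum(me1$placements == "prop"), 2)
  expect_true("me1" %in% me1$placements)
  expect_error(apply_propionylation(un), "already")
})

test_that("mass additivity: each placement adds exactly its delta", {
  base <- peptide_form("KSTGGKAPR")
  for (mod in c("ac", "me1", "me2", "me3")) {
    with_mod <- peptide_form("KSTGGKAPR", c("6" = mod))
    expect_equal(monoisotopic_mass(with_mod) - monoisotopic_mass(base),
                 modification_delta(mod), tolerance = 1e-10)
  }
  ph <- peptide_form("KSTGGKAPR", c("2" = "ph"))
  expect_equal(monoisotopic_mass(ph) - monoisotopic_mass(base),
               modification_delta("ph"), tolerance = 1e-10)
})

test_that("precursor m/z follows the proton convention", {
  expect_equal(precursor_mz(100, 1), 101.007276, tolerance = 1e-6)
  # derivatized mono-acetyl H4 4-17 at charge 2
  k8 <- apply_propionylation(
    peptide_form("GKGGKGLGKGGAKR", c("5" = "ac"), protein = "H4",
                 start = 4))
  m <- monoisotopic_mass(k8)
  expect_equal(m, 1535.8783, tolerance = 1e-3)
  expect_equal(round(precursor_mz(m, 2), 4), 768.9465, tolerance = 2e-4)
  expect_error(precursor_mz(100, 0), "charge")
})

test_that("fragment series are complete and complementary", {
  f <- apply_propionylation(
    peptide_form("GKGGKGLGKGGAKR", c("5" = "ac"), protein = "H4",
                 start = 4))
  fr <- fragment_mz_series(f)
  m <- monoisotopic_mass(f)
  n <- nchar(f$sequence)
  # full-length y ion equals the singly charged precursor
  yfull <- fr$mz[fr$ion == "y" & fr$index == n]
  expect_equal(yfull, precursor_mz(m, 1), tolerance = 1e-9)
  # b_i + y_(n-i) neutral masses sum to the precursor neutral mass
  for (i in 1:(n - 1)) {
    b <- fr$neutral[fr$ion == "b" & fr$index == i]
    y <- fr$neutral[fr$ion == "y" & fr$index == n - i]
    expect_equal(b + y, m, tolerance = 1e-9)
  }
})

test_that("positional isomers differ by prop - ac on spanning fragments", {
  k8 <- apply_propionylation(
    peptide_form("GKGGKGLGKGGAKR", c("5" = "ac"), start = 4,
                 protein = "H4"))
  k5 <- apply_propionylation(
    peptide_form("GKGGKGLGKGGAKR", c("2" = "ac"), start = 4,
                 protein = "H4"))
  y10_k8 <- fragment_mz_series(k8)
  y10_k5 <- fragment_mz_series(k5)
  d <- y10_k8$mz[y10_k8$ion == "y" & y10_k8$index == 10] -
    y10_k5$mz[y10_k5$ion == "y" & y10_k5$index == 10]
  expect_equal(abs(d), modification_delta("prop") - modification_delta("ac"),
               tolerance = 1e-6)
  expect_equal(round(abs(d), 4), 14.0157)
})

test_that("isotope envelopes match a brute-force enumeration oracle", {
  # water: M0 dominates
  env_w <- isotope_envelope("H2O", charge = 1, n_peaks = 3)
  expect_equal(env_w$intensity[1], 1)
  expect_lt(env_w$intensity[2], 0.01)
  # spacing at charge 2
  f <- apply_propionylation(
    peptide_form("GKGGKGLGKGGAKR", c("5" = "ac")))
  env <- isotope_envelope(f, charge = 2, n_peaks = 3)
  expect_equal(diff(env$mz), rep(1.0033548378 / 2, 2), tolerance = 1e-9)
  expect_equal(round(diff(env$mz)[1], 4), 0.5017)
  # intensities vs the enumeration oracle, within 1% relative
  comp <- form_composition(f)
  expect_equal(env$intensity, oracle_isotope_dist(comp, 3),
               tolerance = 0.01)
  # methionine-containing peptide exercises sulfur
  fm <- peptide_form("AMSK")
  expect_equal(isotope_envelope(fm, 1, 4)$intensity,
               oracle_isotope_dist(form_composition(fm), 4),
               tolerance = 0.01)
  expect_true(all(env$intensity >= 0))
})
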