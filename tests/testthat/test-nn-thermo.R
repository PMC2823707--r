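# Nearest-neighbor parameter sets, duplex thermodynamics, corrected Tm.

test_that("parameter sets load complete, validated tables", {
  dna <- ps_dna()
  expect_s3_class(dna, "nn_param_set")
  expect_equal(nrow(dna$stacks), 16L)
  # DNA/DNA stacks are symmetric under reverse-complement of the key
  g <- setNames(dna$stacks$dH, dna$stacks$stack)
  for (key in dna$stacks$stack) {
    rc <- revcomp(key)
    expect_equal(g[[key]], g[[rc]], label = paste("dH", key, "vs", rc))
  }
  expect_error(load_parameter_set("XNA/DNA"), "unknown parameter set")
})

test_that("hybrid table is orientation-specific and matches its packaged file", {
  hyb <- ps_hyb()
  path <- system.file("extdata", "params", "stack_rna_dna.tsv",
                      package = "hybtherm")
  raw <- read.table(path, comment.char = "#",
                    col.names = c("stack", "dH", "dS"),
                    stringsAsFactors = FALSE)
  raw <- raw[raw$stack != "init", ]
  # entry-by-entry round trip of the packaged text table
  m <- merge(hyb$stacks, raw, by = "stack")
  expect_equal(nrow(m), 16L)
  expect_equal(m$dH.x, m$dH.y)
  expect_equal(m$dS.x, m$dS.y)
  # not symmetric under reverse-complement (e.g. rAA/dTT vs rUU/dAA)
  g <- setNames(hyb$stacks$dH, hyb$stacks$stack)
  expect_false(isTRUE(all.equal(g[["AA"]], g[["UU"]])))
})

test_that("duplex dH/dS equal an independent table-lookup summation", {
  path <- system.file("extdata", "params", "stack_dna_dna.tsv",
                      package = "hybtherm")
  raw <- read.table(path, comment.char = "#",
                    col.names = c("stack", "dH", "dS"),
                    stringsAsFactors = FALSE)
  dH <- setNames(raw$dH, raw$stack); dS <- setNames(raw$dS, raw$stack)
  set.seed(11)
  for (rep in 1:5) {
    s <- random_seq(sample(10:40, 1))
    chars <- strsplit(s, "")[[1]]
    keys <- paste0(chars[-length(chars)], chars[-1])
    dx <- duplex_thermo(s, "DNA/DNA")
    expect_equal(dx$dH, sum(dH[keys]) + dH[["init"]])
    expect_equal(dx$dS, sum(dS[keys]) + dS[["init"]])
    expect_equal(dx$n_stacks, nchar(s) - 1L)
    # consistency identity
    expect_equal(dx$dG_at_T, dx$dH - 310.15 * dx$dS / 1000,
                 tolerance = 1e-9)
    expect_lt(dx$dG_at_T, 0)
    # antiparallel symmetry: the reverse complement is the same duplex
    expect_equal(duplex_thermo(revcomp(s), "DNA/DNA")$dG_at_T, dx$dG_at_T)
  }
})

test_that("degenerate and invalid probe input is rejected", {
  expect_error(duplex_thermo("A", "DNA/DNA"), "degenerate")
  expect_error(duplex_thermo("ACGTN", "DNA/DNA"), "invalid")
  expect_error(duplex_thermo("ACGU", "DNA/DNA"), "invalid")
})

test_that("formamide correction is exactly linear at 0.63 degC per percent", {
  dx <- duplex_thermo(strrep("ACGT", 10), "DNA/DNA")
  tm0 <- melting_temperature(dx, thermo_conditions(formamide_pct = 0))
  for (f in c(1, 10, 35, 50)) {
    tmf <- melting_temperature(dx, thermo_conditions(formamide_pct = f))
    expect_equal(tmf - tm0, -0.63 * f, tolerance = 1e-12)
  }
  # the hybridization protocol's 35 % depress Tm by 22.05 degC
  tm35 <- melting_temperature(dx, thermo_conditions(formamide_pct = 35))
  expect_equal(tm0 - tm35, 22.05, tolerance = 1e-12)
})

test_that("salt term vanishes at 1 M sodium and is monotone below", {
  dx <- duplex_thermo(strrep("GATC", 12), "DNA/DNA")
  cond1 <- thermo_conditions(sodium = 1)
  expect_equal(melting_temperature(dx, cond1),
               melting_temperature(dx, cond1, salt_correction = FALSE))
  nas <- c(0.05, 0.1, 0.3, 0.6, 1)
  tms <- vapply(nas, function(na)
    melting_temperature(dx, thermo_conditions(sodium = na)), numeric(1))
  expect_true(all(diff(tms) > 0))
})

test_that("doubling strand concentration shifts Tm by the closed-form amount", {
  dx <- duplex_thermo(strrep("AGCT", 9), "DNA/DNA")
  ct <- 6.1e-17
  c1 <- thermo_conditions(strand_conc = ct)
  c2 <- thermo_conditions(strand_conc = 2 * ct)
  R <- 1.987
  den1 <- dx$dS + c1$helix_init_A + R * log(ct / 4)
  den2 <- den1 + R * log(2)
  expected <- 1000 * dx$dH / den2 - 1000 * dx$dH / den1
  expect_equal(melting_temperature(dx, c2) - melting_temperature(dx, c1),
               expected, tolerance = 1e-9)
})

test_that("correction terms toggle independently to the bare two-state Tm", {
  dx <- duplex_thermo(strrep("TGCA", 11), "DNA/DNA")
  cond <- thermo_conditions(formamide_pct = 35, sodium = 0.6)
  bare <- 1000 * dx$dH /
    (dx$dS + cond$helix_init_A + 1.987 * log(cond$strand_conc / 4)) - 273.15
  expect_equal(melting_temperature(dx, cond, salt_correction = FALSE,
                                   formamide_correction = FALSE), bare)
  expect_equal(melting_temperature(dx, cond, formamide_correction = FALSE),
               bare + 16.6 * log10(0.6))
  expect_equal(melting_temperature(dx, cond, salt_correction = FALSE),
               bare - 0.63 * 35)
  # C_t / 1 convention switch moves the denominator as expected
  cond_ct1 <- thermo_conditions(ct_divisor = 1)
  expect_gt(abs(melting_temperature(dx, cond_ct1) -
                melting_temperature(dx, thermo_conditions())), 0)
})

test_that("non-negative Tm denominator is reported as a domain error", {
  dx <- duplex_thermo(strrep("ACGT", 10), "DNA/DNA")
  expect_error(
    melting_temperature(dx, thermo_conditions(helix_init_A = 1e6)),
    "denominator")
})

test_that("condition validation rejects non-physical inputs", {
  expect_error(thermo_conditions(sodium = 0), "sodium")
  expect_error(thermo_conditions(formamide_pct = -1), "formamide")
  expect_error(thermo_conditions(strand_conc = 0), "strand_conc")
})

test_that("synthesis yield compounds the stepwise efficiency", {
  expect_equal(synthesis_yield(60, 0.98), 0.98^60)
  expect_lt(synthesis_yield(60, 0.98), 0.30)
  expect_equal(synthesis_yield(1, 0.5), 0.5)
})
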