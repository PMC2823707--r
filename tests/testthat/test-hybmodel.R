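# Probe bookkeeping, exact-match mapping, fragment extraction, the
# effective interaction energy, truncations and intensity summaries.

test_that("probes map iff their reverse complement occurs exactly once", {
  site <- "ACGTACGTTGCAGCATCGGATCGATCGG"       # 28 nt
  t1 <- paste0(strrep("A", 30), site, strrep("T", 30))
  t2 <- paste0(strrep("G", 20), site, strrep("C", 20))
  t3 <- paste0(strrep("A", 10), site, strrep("C", 5), site)
  probe_seq <- revcomp(site)
  probes <- data.frame(
    probe_id = c("hit", "multi_t", "none", "multi_l"),
    seq = c(probe_seq, probe_seq, strrep("ACGT", 7), probe_seq))

  m1 <- map_probes(probes[c(1, 3), ], c(tA = t1))
  expect_equal(m1$entries$probe_id, "hit")
  expect_equal(m1$entries$start, 30)
  expect_equal(m1$entries$end, 58)
  expect_equal(m1$excluded$reason, "no_match")

  m2 <- map_probes(probes[2, , drop = FALSE], c(tA = t1, tB = t2))
  expect_equal(m2$excluded$reason, "multi_target")

  m3 <- map_probes(probes[4, , drop = FALSE], c(tC = t3))
  expect_equal(m3$excluded$reason, "multi_locus")

  expect_error(map_probes(rbind(probes, probes[1, ]), c(tA = t1)),
               "duplicate probe ids")
})

test_that("fragments carry the re-indexed binding site and clipped flanks", {
  tg <- strrep("ACGT", 500)                     # 2000 nt
  fr <- extract_fragment(tg, c(1000, 1060))
  expect_equal(nchar(fr$seq), 460)
  expect_equal(fr$binding_site, c(200, 260))
  expect_equal(fr$seq, substr(tg, 801, 1260))
  # left flank truncated at the target start
  fr2 <- extract_fragment(tg, c(10, 70))
  expect_equal(fr2$left_flank, 10)
  expect_equal(fr2$binding_site, c(10, 70))
  # site covering the whole target
  fr3 <- extract_fragment("ACGTACGTAC", c(0, 10))
  expect_equal(fr3$seq, "ACGTACGTAC")
  expect_equal(fr3$left_flank, 0)
  expect_equal(fr3$right_flank, 0)
  expect_error(extract_fragment("ACGT", c(2, 10)), "bounds")
  # substring identity and idempotence in fragment coordinates
  bs <- substr(fr$seq, fr$binding_site[1] + 1, fr$binding_site[2])
  expect_equal(bs, substr(tg, 1001, 1060))
})

test_that("energy profile obeys the effective-interaction-energy algebra", {
  set.seed(3)
  tg <- c(t1 = random_seq(400))
  win <- substr(tg[[1]], 101, 160)
  pr <- probe("p1", revcomp(win))
  fr <- extract_fragment(tg[[1]], c(100, 160))
  ep <- energy_profile(pr, fr, "DNA")
  expect_equal(ep$dG, ep$dG_h - ep$dG_p - ep$dG_t - ep$dG_pp)
  expect_gte(ep$dG, ep$dG_h)
  expect_lte(ep$dG_h, 0)
  expect_lte(ep$dG_p, 0)
  expect_lte(ep$dG_t, 0)
  expect_lte(ep$dG_pp, 0)
  # a probe that is not the site's complement names the first mismatch
  bad <- probe("p2", revcomp(paste0("T", substr(win, 2, 60))))
  expect_error(energy_profile(bad, fr, "DNA"), "mismatch at site position 1")
})

test_that("the full profile matches an all-oracle recomputation on a toy pair", {
  # toy scale: every term is recomputable by exhaustive enumeration
  # (the probe object is built directly to stay in the enumerable regime)
  target <- c(tt = "GGAATCCGGATCGAAGCCAT")
  site <- c(4, 16)
  site_seq <- substr(target[[1]], 5, 16)
  pr <- structure(list(id = "toy", seq = revcomp(site_seq),
                       solution_end = "5prime", tethered_end = "3prime",
                       linker_len = 0L), class = "hyb_probe")
  fr <- extract_fragment(target[[1]], site, flank = 200)
  ep <- energy_profile(pr, fr, "DNA")

  en_probe <- enumerate_structures(pr$seq, ps_dna())
  dG_p <- -RT37 * log(sum(exp(-en_probe$energy / RT37)))
  dG_t <- -oracle_opening(fr$seq, fr$binding_site, ps_dna())
  dG_pp <- hybtherm:::enumerate_dimer_energy(pr$seq, pr$seq, ps_dna())
  dG_h <- min(0, duplex_thermo(pr$seq, "DNA/DNA")$dG_at_T)
  expect_equal(ep$dG_p, dG_p, tolerance = 1e-6)
  expect_equal(ep$dG_t, dG_t, tolerance = 1e-6)
  expect_equal(ep$dG_pp, dG_pp, tolerance = 1e-6)
  expect_equal(ep$dG, dG_h - dG_p - dG_t - dG_pp, tolerance = 1e-6)
})

test_that("RNA targets route through the hybrid duplex and RNA folding", {
  set.seed(8)
  tg_rna <- c(r1 = random_seq(200, "RNA"))
  win <- substr(tg_rna[[1]], 51, 90)
  pr <- probe("p1", revcomp(win, "RNA", "DNA"))
  fr <- extract_fragment(tg_rna[[1]], c(50, 90))
  ep <- energy_profile(pr, fr, "RNA")
  hyb <- duplex_thermo(pr$seq, "RNA/DNA")
  expect_equal(ep$dG_h, min(0, hyb$dG_at_T))
  # Tm stays the DNA-duplex melting temperature of the probe
  dna <- duplex_thermo(pr$seq, "DNA/DNA")
  expect_equal(ep$Tm, melting_temperature(dna, thermo_conditions()))
})

test_that("truncations preserve orientation and nest", {
  s <- paste0(strrep("ACGTT", 11), "GGGCC")     # 60-mer
  p <- probe("p1", s)
  t3 <- truncate_probe(p, "tethered_3prime", 5)
  expect_equal(t3$seq, substr(s, 1, 55))        # 5' (solution) end kept
  expect_equal(t3$id, "p1_3p5")
  t5 <- truncate_probe(p, "solution_5prime", 20)
  expect_equal(t5$seq, substr(s, 21, 60))       # 3' (tethered) end kept
  # 3':10 equals 3':5 applied twice
  t10 <- truncate_probe(p, "tethered_3prime", 10)
  twice <- truncate_probe(truncate_probe(p, "tethered_3prime", 5),
                          "tethered_3prime", 5)
  expect_equal(t10$seq, twice$seq)
  expect_error(truncate_probe(p, "tethered_3prime", 60), "degenerate")
})

test_that("truncation never strengthens the duplex", {
  set.seed(13)
  for (i in 1:10) {
    s <- random_seq(sample(45:75, 1))
    full <- abs(duplex_thermo(s, "DNA/DNA")$dG_at_T)
    for (end in c("solution_5prime", "tethered_3prime"))
      for (ntr in c(5, 10, 20)) {
        tp <- truncate_probe(probe("p", s), end, ntr)
        expect_lte(abs(duplex_thermo(tp$seq, "DNA/DNA")$dG_at_T), full)
      }
  }
})

test_that("expression filter thresholds at the mean over mapped probes", {
  map <- structure(list(
    entries = data.frame(probe_id = paste0("p", 1:6),
                         target_id = rep(c("a", "b", "c"), each = 2),
                         start = 0L, end = 10L, strand = "+"),
    excluded = data.frame(probe_id = "px", reason = "no_match")),
    class = "probe_target_map")
  # all equal: nothing strictly exceeds the mean
  eq <- data.frame(probe_id = paste0("p", 1:6), intensity = rep(5, 6))
  expect_length(as.character(expression_filter(eq, map)), 0)
  # one bright target dominates
  it <- data.frame(probe_id = paste0("p", 1:6),
                   intensity = c(10, 10, 100, 10, 10, 10))
  ex <- expression_filter(it, map)
  expect_equal(as.character(ex), "b")
  expect_equal(attr(ex, "threshold"), mean(it$intensity))
  expect_error(expression_filter(data.frame(probe_id = "q",
                                            intensity = 1), map),
               "no mapped probe")
})

test_that("expression filter recovers a simulated two-population mixture", {
  cfg <- sim_config("cdna", seed = 99, n_targets = 30,
                    target_length = c(150, 250), frac_expressed = 0.5)
  tg <- random_targets(cfg)
  pr <- tile_probes(tg, cfg)
  prof <- profile_probes(pr[, c("probe_id", "seq")], tg, "DNA",
                         cfg$conditions)
  it <- simulate_intensities(prof, cfg)
  recovered <- sort(as.character(expression_filter(it, attr(prof, "map"))))
  expect_equal(recovered, attr(it, "expressed"))
})

test_that("variation statistic is the per-target log2 max/min ratio", {
  map <- structure(list(
    entries = data.frame(probe_id = paste0("p", 1:4),
                         target_id = rep(c("a", "b"), each = 2),
                         start = 0L, end = 10L, strand = "+"),
    excluded = data.frame(probe_id = character(0),
                          reason = character(0))),
    class = "probe_target_map")
  it <- data.frame(probe_id = paste0("p", 1:4),
                   intensity = c(100, 1800, 7, 7))
  vs <- variation_stats(it, map)
  expect_equal(sort(vs$per_target$log2_ratio), c(0, log2(18)))
  expect_equal(vs$mean_log2_ratio, mean(c(log2(18), 0)))
  expect_error(variation_stats(transform(it, intensity = c(1, -1, 1, 1)),
                               map), "non-positive")
})
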