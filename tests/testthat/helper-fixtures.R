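# Shared fixtures: parameter sets loaded once, small sequence generators,
# and the (lazily built, memoised) synthetic benchmark used by the
# acceptance checks.

.fixture_env <- new.env(parent = emptyenv())

ps_dna <- function() {
  if (is.null(.fixture_env$dna))
    .fixture_env$dna <- load_parameter_set("DNA/DNA")
  .fixture_env$dna
}
ps_rna <- function() {
  if (is.null(.fixture_env$rna))
    .fixture_env$rna <- load_parameter_set("RNA/RNA")
  .fixture_env$rna
}
ps_hyb <- function() {
  if (is.null(.fixture_env$hyb))
    .fixture_env$hyb <- load_parameter_set("RNA/DNA")
  .fixture_env$hyb
}

random_seq <- function(n, alphabet = "DNA") {
  letters4 <- if (alphabet == "RNA") c("A", "C", "G", "U")
              else c("A", "C", "G", "T")
  paste(sample(letters4, n, replace = TRUE), collapse = "")
}

RT37 <- 1.987e-3 * 310.15

# opening energy from the enumeration oracle: constrain the region
# (0-based half-open) to be unpaired and compare ensemble weights.
oracle_opening <- function(seq, region, params, temperature = 37) {
  en <- enumerate_structures(seq, params, temperature)
  RT <- 1.987e-3 * (temperature + 273.15)
  touches <- vapply(en$structure, function(db) {
    p <- hybtherm:::dotbracket_pairs(db)
    if (!nrow(p)) return(FALSE)
    any((p[, 1] > region[1] & p[, 1] <= region[2]) |
        (p[, 2] > region[1] & p[, 2] <= region[2]))
  }, logical(1), USE.NAMES = FALSE)
  Z <- sum(exp(-en$energy / RT))
  Zc <- sum(exp(-en$energy[!touches] / RT))
  RT * (log(Z) - log(Zc))
}

# Synthetic benchmark for the model-identity and parameter-recovery
# checks: cDNA-preset tiling probes on short targets.  Built once per
# test run.
acceptance_benchmark <- function() {
  if (!is.null(.fixture_env$bench)) return(.fixture_env$bench)
  cfg <- sim_config("cdna", seed = 424242, n_targets = 1250,
                    target_length = c(150, 300))
  targets <- random_targets(cfg)
  probes <- tile_probes(targets, cfg)
  profiles <- profile_probes(probes[, c("probe_id", "seq")], targets,
                             target_chemistry = cfg$target_chemistry,
                             conditions = cfg$conditions)
  .fixture_env$bench <- list(cfg = cfg, targets = targets,
                             probes = probes, profiles = profiles)
  .fixture_env$bench
}

# Steric simulation: fixed-length 60-mers whose signal is generated from
# the effective interaction energy of the probe *minus its 5 tethered
# bases* (those bases carry zero weight, emulating surface inaccessibility).
# Returns the truncation-scan summary plus paired-bootstrap standard
# errors for the correlation differences.
steric_scan_fixture <- function() {
  if (!is.null(.fixture_env$steric)) return(.fixture_env$steric)
  cfg_s <- sim_config("cdna", seed = 606, n_targets = 250,
                      target_length = c(150, 300), probe_length = 60,
                      noise_sigma = 0.2)
  targets <- random_targets(cfg_s)
  probes <- tile_probes(targets, cfg_s)
  prof_full <- profile_probes(probes[, c("probe_id", "seq")], targets,
                              target_chemistry = "DNA",
                              conditions = cfg_s$conditions)
  # generator: the 3':5-truncated probe against the matching shrunk site
  gen_map <- structure(list(
    entries = data.frame(probe_id = prof_full$probe_id,
                         target_id = prof_full$target_id,
                         start = prof_full$site_start + 5L,
                         end = prof_full$site_end, strand = "+",
                         stringsAsFactors = FALSE),
    excluded = data.frame(probe_id = character(0),
                          reason = character(0))),
    class = "probe_target_map")
  gen_probes <- data.frame(probe_id = prof_full$probe_id,
                           seq = substr(prof_full$seq, 1L,
                                        nchar(prof_full$seq) - 5L),
                           stringsAsFactors = FALSE)
  prof_gen <- profile_probes(gen_probes, targets,
                             target_chemistry = "DNA",
                             conditions = cfg_s$conditions, map = gen_map)
  intens <- simulate_intensities(prof_gen, cfg_s)
  rc <- run_config(out_dir = file.path(tempdir(), "hybtherm-steric"),
                   conditions = cfg_s$conditions, truncations = 5L,
                   target_chemistry = "DNA")
  scan <- cli_truncate_scan(rc, profiles = prof_full,
                            intensities = intens, targets = targets)
  vd <- attr(scan, "variant_dG")
  boot <- replicate(200, {
    idx <- sample.int(nrow(vd), replace = TRUE)
    vapply(c("full", "3p:5", "5p:5"), function(v)
      abs(stats::cor(vd[[v]][idx], vd$intensity[idx],
                     method = "spearman")), numeric(1))
  })
  .fixture_env$steric <- list(
    summary = scan,
    se_full_3p5 = stats::sd(boot["full", ] - boot["3p:5", ]),
    se_full_5p5 = stats::sd(boot["full", ] - boot["5p:5", ]))
  .fixture_env$steric
}

# Small simulated data set written to disk for the CLI round-trips.
small_sim_dir <- function() {
  if (!is.null(.fixture_env$simdir)) return(.fixture_env$simdir)
  out <- file.path(tempdir(), "hybtherm-small-sim")
  sim <- sim_config("cdna", seed = 77, n_targets = 8,
                    target_length = c(150, 250))
  cfg <- run_config(out_dir = out, seed = 3, n_rep = 5, sim = sim,
                    conditions = sim$conditions)
  cli_simulate(cfg)
  .fixture_env$simdir <- list(dir = out, config = cfg)
  .fixture_env$simdir
}
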