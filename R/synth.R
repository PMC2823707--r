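#' Simulation configuration
#'
#' Parameters of the synthetic benchmark: random targets, tiling probes
#' and Langmuir-type intensity simulation.  Two presets mirror the two
#' tiling-array regimes the model is aimed at: `"cdna"` (45–75-mer probes
#' at 22 nt resolution on cDNA targets) and `"rrna"` (25-mers at 1 nt
#' resolution on nine RNA targets).
#'
#' The intensity model is a saturating isotherm on the effective
#' interaction energy: occupancy
#' `theta = 1 / (1 + exp(beta * (dG - dG_half)))`, signal
#' `I = scale * theta + background`, multiplied by lognormal noise
#' `exp(N(0, sigma))`.  `dG_half` is the energy of half-saturation and
#' `beta` the energy sensitivity in 1/(kcal/mol) — an effective inverse
#' temperature absorbing the non-equilibrium washing and labelling steps
#' that flatten the thermodynamic response of real arrays.  With
#' `driver = "Tm"` the signal is driven by the melting temperature
#' instead (the non-specific regime), via
#' `theta = 1 / (1 + exp(-(Tm - tm_half) / tm_width))`.
#'
#' @param preset `"cdna"` or `"rrna"`.
#' @param seed integer seed (mandatory; every generator call is
#'   deterministic given the config).
#' @param n_targets number of targets.
#' @param target_length length-2 range of target lengths (nt).
#' @param gc GC fraction in (0, 1).
#' @param tiling_step tiling resolution (nt).
#' @param probe_length length-2 range (probe lengths drawn uniformly) or
#'   a single fixed length.
#' @param target_chemistry `"DNA"` or `"RNA"`.
#' @param frac_expressed fraction of targets carrying signal; the rest
#'   get background only.
#' @param scale,background Langmuir scale and additive background
#'   (fluorescence units).
#' @param noise_sigma lognormal noise sd (natural-log scale).
#' @param dG_half,beta isotherm midpoint (kcal/mol) and sensitivity
#'   (1/(kcal/mol)).
#' @param driver `"dG"` or `"Tm"`: which energy term generates signal.
#' @param tm_half,tm_width midpoint (°C) and width (°C) of the Tm driver.
#' @param conditions [thermo_conditions()] used when profiling; default
#'   is the array protocol with 35 % formamide.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(preset = c("cdna", "rrna"), seed,
                       n_targets = NULL, target_length = NULL, gc = 0.5,
                       tiling_step = NULL, probe_length = NULL,
                       target_chemistry = NULL,
                       frac_expressed = 1,
                       scale = 10000, background = 100,
                       noise_sigma = 0.4,
                       dG_half = NULL, beta = NULL,
                       driver = c("dG", "Tm"),
                       tm_half = NULL, tm_width = NULL,
                       conditions = thermo_conditions(formamide_pct = 35)) {
  preset <- match.arg(preset)
  driver <- match.arg(driver)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be inside (0, 1)", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  # isotherm midpoints sit at the preset's typical effective interaction
  # energy (target concentration is a free parameter of the experiments);
  # Tm midpoints likewise at the typical probe Tm of the preset.
  def <- switch(preset,
    cdna = list(n_targets = 60L, target_length = c(500L, 1500L),
                tiling_step = 22L, probe_length = c(45L, 75L),
                target_chemistry = "DNA",
                dG_half = -65, beta = 0.15, tm_half = 50, tm_width = 6),
    rrna = list(n_targets = 9L, target_length = c(1200L, 1800L),
                tiling_step = 1L, probe_length = c(25L, 25L),
                target_chemistry = "RNA",
                dG_half = -20, beta = 0.5, tm_half = 22, tm_width = 5))
  pl <- probe_length %||% def$probe_length
  if (length(pl) == 1L) pl <- c(pl, pl)
  structure(list(preset = preset,
                 seed = as.integer(seed),
                 n_targets = as.integer(n_targets %||% def$n_targets),
                 target_length = as.integer(target_length %||%
                                            def$target_length),
                 gc = gc,
                 tiling_step = as.integer(tiling_step %||% def$tiling_step),
                 probe_length = as.integer(pl),
                 target_chemistry = target_chemistry %||%
                   def$target_chemistry,
                 frac_expressed = frac_expressed,
                 scale = scale, background = background,
                 noise_sigma = noise_sigma,
                 dG_half = dG_half %||% def$dG_half,
                 beta = beta %||% def$beta,
                 driver = driver,
                 tm_half = tm_half %||% def$tm_half,
                 tm_width = tm_width %||% def$tm_width,
                 conditions = conditions),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config '%s' (seed %d): %d %s targets %d-%d nt, %d-%d-mer probes at %d nt steps\n",
    x$preset, x$seed, x$n_targets, x$target_chemistry,
    x$target_length[1], x$target_length[2],
    x$probe_length[1], x$probe_length[2], x$tiling_step))
  cat(sprintf(
    "  driver %s, scale %g, background %g, sigma %g, expressed %g\n",
    x$driver, x$scale, x$background, x$noise_sigma, x$frac_expressed))
  invisible(x)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Random target sequences
#'
#' i.i.d. random targets at the configured GC content and length range;
#' deterministic under the config seed.
#'
#' @param config a [sim_config()] object.
#' @return named character vector of target sequences (with U for RNA
#'   chemistry), one element per target.
#' @export
random_targets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  letters4 <- alphabet_letters(config$target_chemistry)
  prob <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
            G = config$gc / 2, T = (1 - config$gc) / 2)
  if (config$n_targets == 0L)
    return(stats::setNames(character(0), character(0)))
  with_seed(config$seed, {
    len_pool <- config$target_length[1]:config$target_length[2]
    lens <- if (length(len_pool) == 1L)
      rep(len_pool, config$n_targets)
    else sample(len_pool, config$n_targets, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(letters4, L, replace = TRUE, prob = prob), collapse = ""),
      character(1))
    names(seqs) <- sprintf("target_%03d", seq_len(config$n_targets))
    seqs
  })
}

#' Tiling probe set
#'
#' Generates probes tiling each target at the configured step: each probe
#' is the reverse complement (DNA alphabet) of a target window, with
#' length drawn uniformly from the configured range.  Probes that do not
#' map uniquely across the target set (multi-locus / multi-target) are
#' dropped; the count is reported and recorded in attribute `"dropped"`.
#'
#' @param targets named character vector from [random_targets()].
#' @param config the same [sim_config()].
#' @return data frame with columns `probe_id`, `seq`, `target_id`,
#'   `start`, `end` (0-based half-open window on the target).
#' @export
tile_probes <- function(targets, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(targets)) stop("targets must be non-empty", call. = FALSE)
  chem <- config$target_chemistry
  rows <- list()
  with_seed(config$seed + 1L, {
    for (tid in names(targets)) {
      L <- nchar(targets[[tid]])
      if (L < config$probe_length[1]) {
        warning("target ", tid, " shorter than the probe length; skipped")
        next
      }
      start <- 0L
      len_pool <- config$probe_length[1]:config$probe_length[2]
      while (TRUE) {
        len <- if (length(len_pool) == 1L) len_pool else
          sample(len_pool, 1L)
        if (start + len > L) break
        window <- substr(targets[[tid]], start + 1L, start + len)
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = sprintf("%s_p%05d", tid, start),
          seq = revcomp(window, chem, "DNA"),
          target_id = tid, start = start, end = start + len,
          stringsAsFactors = FALSE)
        start <- start + config$tiling_step
      }
    }
  })
  probes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(0), seq = character(0),
               target_id = character(0), start = integer(0),
               end = integer(0))
  # keep only probes whose sequence maps uniquely on this target set
  map <- map_probes(probes[, c("probe_id", "seq")], targets)
  keep <- probes$probe_id %in% map$entries$probe_id
  dropped <- sum(!keep)
  if (dropped > 0L)
    message("tile_probes: dropped ", dropped,
            " non-uniquely mapping probes")
  out <- probes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Simulated probe intensities
#'
#' Saturating-isotherm intensity simulation on a set of energy profiles
#' (see [sim_config()] for the model).  Probes of non-expressed targets
#' receive background-only signal.  Deterministic under the config seed.
#'
#' @param profiles data frame from [profile_probes()] (columns
#'   `probe_id`, `target_id`, and the driver column `dG` or `Tm`).
#' @param config a [sim_config()].
#' @return data frame with `probe_id`, `intensity` (strictly positive);
#'   attributes `"expressed"` (target ids with signal) and `"scale_flag"`
#'   (`"linear"`).
#' @export
simulate_intensities <- function(profiles, config) {
  stopifnot(inherits(config, "sim_config"),
            all(c("probe_id", "target_id") %in% names(profiles)))
  driver_col <- config$driver
  if (!driver_col %in% names(profiles))
    stop("profiles lack the driver column '", driver_col, "'",
         call. = FALSE)
  with_seed(config$seed + 2L, {
    tids <- unique(profiles$target_id)
    n_exp <- round(config$frac_expressed * length(tids))
    expressed <- sort(sample(tids, n_exp))
    theta <- if (config$driver == "dG")
      stats::plogis(-config$beta * (profiles$dG - config$dG_half))
    else
      stats::plogis((profiles$Tm - config$tm_half) / config$tm_width)
    mu <- ifelse(profiles$target_id %in% expressed,
                 config$scale * theta + config$background,
                 config$background)
    noise <- if (config$noise_sigma > 0)
      exp(stats::rnorm(nrow(profiles), 0, config$noise_sigma)) else 1
    out <- data.frame(probe_id = profiles$probe_id,
                      intensity = mu * noise,
                      stringsAsFactors = FALSE)
    attr(out, "expressed") <- expressed
    attr(out, "scale_flag") <- "linear"
    out
  })
}
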