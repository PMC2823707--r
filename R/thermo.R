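#' Hybridization conditions
#'
#' Bundle of the physico-chemical conditions entering the duplex free
#' energy and the corrected melting temperature.  Defaults reproduce the
#' maskless-synthesis cDNA tiling protocol: 0.6 M sodium, helix-initiation
#' factor A = -10.8 cal/(K·mol), total oligonucleotide concentration
#' C_t = 6.1e-17 M, formamide correction of 0.63 °C per 1 % formamide and
#' R = 1.987 cal/(K·mol).
#'
#' @param temperature working temperature in °C (duplex dG and folding).
#' @param sodium molar sodium concentration, > 0.
#' @param formamide_pct percent (v/v) formamide, >= 0.
#' @param strand_conc molar total oligonucleotide concentration C_t, > 0.
#' @param helix_init_A helix initiation factor, cal/(K·mol).
#' @param formamide_slope °C of Tm depression per 1 % formamide.
#' @param ct_divisor divisor of C_t inside the logarithm of the Tm
#'   equation: 4 for non-self-complementary duplexes (the default
#'   convention), 1 to use C_t directly.
#' @return an object of class `thermo_conditions`.
#' @examples
#' thermo_conditions()                       # the default hybridization buffer
#' thermo_conditions(formamide_pct = 35)     # with 35 % formamide
#' @export
thermo_conditions <- function(temperature = 37,
                              sodium = 0.6,
                              formamide_pct = 0,
                              strand_conc = 6.1e-17,
                              helix_init_A = -10.8,
                              formamide_slope = 0.63,
                              ct_divisor = 4) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (!is.numeric(sodium) || sodium <= 0)
    stop("sodium concentration must be > 0 M", call. = FALSE)
  if (!is.numeric(formamide_pct) || formamide_pct < 0)
    stop("formamide_pct must be >= 0", call. = FALSE)
  if (!is.numeric(strand_conc) || strand_conc <= 0)
    stop("strand_conc must be > 0 M", call. = FALSE)
  if (!ct_divisor %in% c(1, 4))
    stop("ct_divisor must be 1 or 4", call. = FALSE)
  structure(list(temperature = temperature,
                 sodium = sodium,
                 formamide_pct = formamide_pct,
                 strand_conc = strand_conc,
                 helix_init_A = helix_init_A,
                 formamide_slope = formamide_slope,
                 ct_divisor = ct_divisor,
                 gas_constant_R = 1.987),
            class = "thermo_conditions")
}

#' @export
print.thermo_conditions <- function(x, ...) {
  cat("Hybridization conditions:\n")
  cat(sprintf("  T = %g degC, [Na+] = %g M, formamide = %g %%\n",
              x$temperature, x$sodium, x$formamide_pct))
  cat(sprintf("  C_t = %g M (divisor %d), A = %g cal/(K*mol), R = %g cal/(K*mol)\n",
              x$strand_conc, x$ct_divisor, x$helix_init_A, x$gas_constant_R))
  invisible(x)
}

#' Full-length synthesis yield
#'
#' Fraction of probes reaching full length under in-situ synthesis with a
#' given stepwise coupling efficiency: `efficiency^length`.  Maskless
#' array synthesis couples at roughly 96–98 % per base, so even at 98 %
#' fewer than 30 % of 60-mers are full length.
#'
#' @param length probe length (nt).
#' @param efficiency stepwise coupling efficiency in (0, 1].
#' @return full-length fraction in (0, 1].
#' @examples
#' synthesis_yield(60, 0.98)  # < 0.30
#' @export
synthesis_yield <- function(length, efficiency = 0.98) {
  stopifnot(length >= 1, efficiency > 0, efficiency <= 1)
  efficiency^length
}

#' Nearest-neighbor duplex thermodynamics
#'
#' Enthalpy, entropy and free energy of the duplex formed by a probe and
#' its exact antiparallel Watson-Crick complement, as the sum of
#' dinucleotide stack terms plus the parameter set's initiation term.
#' For the `"RNA/DNA"` chemistry the probe is a DNA oligonucleotide and
#' the stack sum runs over the implied RNA target strand (the hybrid
#' table is keyed by the RNA strand 5'→3').
#'
#' @param probe_seq probe sequence 5'→3' (DNA alphabet, or RNA for the
#'   `"RNA/RNA"` chemistry), length >= 2.
#' @param duplex_type `"DNA/DNA"`, `"RNA/RNA"` or `"RNA/DNA"`.
#' @param conditions a [thermo_conditions()] object; sets the temperature
#'   at which `dG_at_T` is evaluated.
#' @param params optional pre-loaded [load_parameter_set()] object
#'   matching `duplex_type` (avoids re-reading the packaged tables).
#' @return object of class `duplex_thermo` with fields `dH` (kcal/mol),
#'   `dS` (cal/(K·mol)), `dG_at_T` (kcal/mol, `dH - T_K*dS/1000`),
#'   `n_stacks`, `duplex_type`, `temperature`.
#' @examples
#' dx <- duplex_thermo("ACGTACGTAC", "DNA/DNA")
#' dx$dG_at_T
#' @export
duplex_thermo <- function(probe_seq, duplex_type = "DNA/DNA",
                          conditions = thermo_conditions(),
                          params = NULL) {
  if (is.null(params)) params <- load_parameter_set(duplex_type)
  stopifnot(inherits(params, "nn_param_set"), params$name == duplex_type)
  probe_alpha <- if (duplex_type == "RNA/RNA") "RNA" else "DNA"
  s <- check_seq(probe_seq, probe_alpha, "probe_seq")
  if (nchar(s) < 2L)
    stop("degenerate input: probe of length ", nchar(s),
         " has no dinucleotide stacks", call. = FALSE)
  # the strand whose 5'->3' dinucleotides key the stack table
  key_strand <- if (duplex_type == "RNA/DNA") revcomp(s, "DNA", "RNA") else s
  chars <- strsplit(key_strand, "", fixed = TRUE)[[1L]]
  keys <- paste0(chars[-length(chars)], chars[-1L])
  dH <- params$stacks$dH; names(dH) <- params$stacks$stack
  dS <- params$stacks$dS; names(dS) <- params$stacks$stack
  sumH <- sum(dH[keys]) + params$init[["dH"]]
  sumS <- sum(dS[keys]) + params$init[["dS"]]
  t_k <- conditions$temperature + 273.15
  structure(list(dH = sumH, dS = sumS,
                 dG_at_T = sumH - t_k * sumS / 1000,
                 n_stacks = length(keys),
                 duplex_type = duplex_type,
                 temperature = conditions$temperature),
            class = "duplex_thermo")
}

#' @export
print.duplex_thermo <- function(x, ...) {
  cat(sprintf("%s duplex: dH = %.2f kcal/mol, dS = %.2f cal/(K*mol)\n",
              x$duplex_type, x$dH, x$dS))
  cat(sprintf("  dG(%g degC) = %.2f kcal/mol over %d stacks\n",
              x$temperature, x$dG_at_T, x$n_stacks))
  invisible(x)
}

#' Corrected melting temperature
#'
#' Two-state melting temperature of a probe/complement duplex with helix
#' initiation, strand concentration, sodium and formamide corrections:
#'
#' \deqn{T_m = \frac{1000\,\Delta H}{\Delta S + A + R \ln(C_t/4)} - 273.15
#'       + 16.6 \log_{10}[Na^+] - 0.63\,F}
#'
#' with \eqn{\Delta H} in kcal/mol, \eqn{\Delta S} and the helix
#' initiation factor A in cal/(K·mol), total strand concentration
#' \eqn{C_t} in mol/l and F the percent formamide.  The formamide term is
#' exactly linear (0.63 °C per 1 % by default) and the salt term vanishes
#' at 1 M sodium.  Salt and formamide corrections can be toggled
#' individually for sensitivity analyses.
#'
#' @param duplex a [duplex_thermo()] object.
#' @param conditions a [thermo_conditions()] object.
#' @param salt_correction,formamide_correction logical; include the
#'   respective correction term.
#' @return melting temperature in °C.
#' @examples
#' dx <- duplex_thermo(paste(rep("ACGT", 10), collapse = ""), "DNA/DNA")
#' melting_temperature(dx, thermo_conditions(formamide_pct = 35))
#' @export
melting_temperature <- function(duplex, conditions = thermo_conditions(),
                                salt_correction = TRUE,
                                formamide_correction = TRUE) {
  stopifnot(inherits(duplex, "duplex_thermo"),
            inherits(conditions, "thermo_conditions"))
  R <- conditions$gas_constant_R
  denom <- duplex$dS + conditions$helix_init_A +
    R * log(conditions$strand_conc / conditions$ct_divisor)
  if (denom >= 0 || !is.finite(denom))
    stop(sprintf(
      "melting temperature undefined: non-negative denominator %.4g (dS=%.4g, A=%.4g, C_t=%.4g)",
      denom, duplex$dS, conditions$helix_init_A, conditions$strand_conc),
      call. = FALSE)
  tm <- 1000 * duplex$dH / denom - 273.15
  if (salt_correction) tm <- tm + 16.6 * log10(conditions$sodium)
  if (formamide_correction)
    tm <- tm - conditions$formamide_slope * conditions$formamide_pct
  tm
}
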