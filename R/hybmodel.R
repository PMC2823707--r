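#' Microarray probe
#'
#' A surface-tethered oligonucleotide probe.  Orientation is fixed by the
#' synthesis chemistry: the 5' end protrudes into solution, the 3' end is
#' attached to the array surface (optionally via a thymidine linker, which
#' is a spacer and excluded from all thermodynamics).
#'
#' @param id probe identifier.
#' @param seq probe sequence 5'→3', DNA alphabet, 25–100 nt.
#' @param linker_len length of the surface linker (not part of `seq`).
#' @return object of class `hyb_probe`.
#' @examples
#' probe("p1", paste(rep("ACGTT", 9), collapse = ""))
#' @export
probe <- function(id, seq, linker_len = 0L) {
  s <- check_seq(seq, "DNA", "probe seq")
  if (nchar(s) < 25L || nchar(s) > 100L)
    stop("probe length ", nchar(s), " outside the accepted 25..100 nt",
         call. = FALSE)
  structure(list(id = as.character(id), seq = s,
                 solution_end = "5prime", tethered_end = "3prime",
                 linker_len = as.integer(linker_len)),
            class = "hyb_probe")
}

#' @export
print.hyb_probe <- function(x, ...) {
  cat(sprintf("probe %s (%d nt, 5' solution / 3' tethered%s)\n  5'-%s-3'\n",
              x$id, nchar(x$seq),
              if (x$linker_len > 0) paste0(", ", x$linker_len, " nt linker")
              else "", x$seq))
  invisible(x)
}

#' Truncate a probe at one end
#'
#' Removes `n` terminal nucleotides from either the solution (5') or the
#' tethered (3') end, preserving orientation.  Used by the truncation
#' scans probing steric accessibility near the array surface.
#'
#' @param probe a [probe()] object.
#' @param end `"solution_5prime"` or `"tethered_3prime"`.
#' @param n number of bases to remove (`n < length`).
#' @return a new `hyb_probe`, id suffixed with the end and `n`
#'   (e.g. `"p1_3p5"`).
#' @examples
#' p <- probe("p1", paste(rep("ACGTT", 12), collapse = ""))
#' truncate_probe(p, "tethered_3prime", 5)
#' @export
truncate_probe <- function(probe, end = c("solution_5prime",
                                          "tethered_3prime"), n) {
  stopifnot(inherits(probe, "hyb_probe"))
  end <- match.arg(end)
  n <- as.integer(n)
  len <- nchar(probe$seq)
  if (n >= len)
    stop("degenerate truncation: removing ", n, " of ", len, " bases",
         call. = FALSE)
  new_seq <- if (end == "tethered_3prime") substr(probe$seq, 1L, len - n)
             else substr(probe$seq, n + 1L, len)
  out <- probe
  out$seq <- new_seq
  out$id <- paste0(probe$id, "_",
                   if (end == "tethered_3prime") "3p" else "5p", n)
  out
}

#' Map probes to targets by exact match
#'
#' A probe maps if and only if its reverse complement occurs as an exact
#' substring of exactly one target, exactly once.  All other probes are
#' excluded with a reason: `no_match` (typical for ~90 % of tiling
#' probes), `multi_locus` (several sites in one target) or `multi_target`
#' (matches to multiple targets).  Matching is against the target
#' sequences as given (the sense strand); coordinates are 0-based
#' half-open.
#'
#' @param probes data frame with columns `probe_id`, `seq`, or a list of
#'   [probe()] objects.
#' @param targets named character vector of target sequences (DNA or RNA
#'   alphabet), e.g. from [read_fasta()].
#' @return object of class `probe_target_map`: list with `entries`
#'   (data frame `probe_id`, `target_id`, `start`, `end`, `strand`) and
#'   `excluded` (data frame `probe_id`, `reason`).
#' @export
map_probes <- function(probes, targets) {
  probes <- as_probe_frame(probes)
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe ids: ",
         probes$probe_id[duplicated(probes$probe_id)][1L], call. = FALSE)
  if (!length(targets)) stop("no targets supplied", call. = FALSE)
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    stop("targets must be named", call. = FALSE)
  targets <- toupper(targets)
  is_rna <- any(grepl("U", targets, fixed = TRUE))
  entries <- list(); excluded <- list()
  for (r in seq_len(nrow(probes))) {
    rc <- revcomp(probes$seq[r], "DNA", if (is_rna) "RNA" else "DNA")
    hits <- lapply(targets, function(tg) {
      m <- gregexpr(rc, tg, fixed = TRUE)[[1L]]
      if (m[1L] == -1L) integer(0) else as.integer(m)
    })
    n_hits <- vapply(hits, length, integer(1))
    tot <- sum(n_hits)
    if (tot == 0L) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(probe_id = probes$probe_id[r], reason = "no_match")
    } else if (sum(n_hits > 0L) > 1L) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(probe_id = probes$probe_id[r], reason = "multi_target")
    } else if (tot > 1L) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(probe_id = probes$probe_id[r], reason = "multi_locus")
    } else {
      tid <- names(which(n_hits == 1L))
      start0 <- hits[[tid]][1L] - 1L
      entries[[length(entries) + 1L]] <-
        data.frame(probe_id = probes$probe_id[r], target_id = tid,
                   start = start0, end = start0 + nchar(rc),
                   strand = "+")
    }
  }
  empty_e <- data.frame(probe_id = character(0), target_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0))
  empty_x <- data.frame(probe_id = character(0), reason = character(0))
  structure(list(entries = if (length(entries))
                   do.call(rbind, entries) else empty_e,
                 excluded = if (length(excluded))
                   do.call(rbind, excluded) else empty_x),
            class = "probe_target_map")
}

#' @export
print.probe_target_map <- function(x, ...) {
  cat("Probe-target map: ", nrow(x$entries), " mapped, ",
      nrow(x$excluded), " excluded\n", sep = "")
  if (nrow(x$excluded))
    print(table(x$excluded$reason))
  invisible(x)
}

as_probe_frame <- function(probes) {
  if (is.data.frame(probes)) {
    stopifnot(all(c("probe_id", "seq") %in% names(probes)))
    data.frame(probe_id = as.character(probes$probe_id),
               seq = toupper(as.character(probes$seq)),
               stringsAsFactors = FALSE)
  } else if (is.list(probes) && all(vapply(probes, inherits, logical(1),
                                           "hyb_probe"))) {
    data.frame(probe_id = vapply(probes, `[[`, character(1), "id"),
               seq = vapply(probes, `[[`, character(1), "seq"),
               stringsAsFactors = FALSE)
  } else stop("probes must be a data frame or a list of hyb_probe objects",
              call. = FALSE)
}

#' Extract a target fragment around a binding site
#'
#' Cuts the probe binding site plus up to `flank` bases of flanking
#' sequence on either side out of the target; bases further away
#' contribute negligibly to structures involving the site.  The binding
#' site is re-indexed into fragment coordinates (0-based half-open).
#'
#' @param target_seq target sequence 5'→3'.
#' @param site integer pair `c(start, end)`, 0-based half-open, on the
#'   target.
#' @param flank maximum flank length on each side (default 200).
#' @param target_id optional identifier carried through.
#' @return object of class `target_fragment` with `seq`, `binding_site`
#'   (fragment coordinates), `left_flank`, `right_flank`, `target_id`.
#' @examples
#' fr <- extract_fragment(strrep("ACGT", 500), c(1000, 1060))
#' fr$binding_site   # c(200, 260)
#' @export
extract_fragment <- function(target_seq, site, flank = 200L,
                             target_id = NA_character_) {
  L <- nchar(target_seq)
  site <- as.integer(site)
  if (length(site) != 2L || site[1L] < 0L || site[2L] > L ||
      site[1L] >= site[2L])
    stop("site [", site[1L], ",", site[2L],
         ") out of bounds for target of length ", L, call. = FALSE)
  fs <- max(0L, site[1L] - as.integer(flank))
  fe <- min(L, site[2L] + as.integer(flank))
  structure(list(target_id = target_id,
                 seq = substr(target_seq, fs + 1L, fe),
                 binding_site = c(site[1L] - fs, site[2L] - fs),
                 left_flank = site[1L] - fs,
                 right_flank = fe - site[2L]),
            class = "target_fragment")
}

#' @export
print.target_fragment <- function(x, ...) {
  cat(sprintf(
    "target fragment (%d nt), binding site [%d,%d), flanks %d/%d%s\n",
    nchar(x$seq), x$binding_site[1L], x$binding_site[2L],
    x$left_flank, x$right_flank,
    if (is.na(x$target_id)) "" else paste0(", target ", x$target_id)))
  invisible(x)
}

# Parameter-set cache shared by profile computations.
param_env <- function() {
  e <- new.env(parent = emptyenv())
  e$folds <- new.env(parent = emptyenv())
  e$get <- function(name) {
    key <- gsub("/", "_", name)
    if (is.null(e[[key]])) e[[key]] <- load_parameter_set(name)
    e[[key]]
  }
  e
}

#' Effective interaction energy profile of one probe
#'
#' The multi-state hybridization model: the free energy gained by
#' probe-target duplex formation, `dG_h`, is reduced by the free energies
#' of the structures competing with it — probe folding (`dG_p`), folding
#' of the binding site in the target (`dG_t`) and probe-probe dimers on
#' the feature (`dG_pp`):
#'
#' \deqn{\Delta G = \Delta G_h - \Delta G_p - \Delta G_t - \Delta G_{pp}}
#'
#' Every competitor term is a (clamped) non-positive free energy: unstable
#' structures contribute zero.  `dG_p` is the sign-flipped ensemble
#' opening cost of the whole probe (`ensemble_dG`), `dG_t` is minus the
#' opening energy of the binding site within the flanked fragment, and
#' `dG_pp` the intermolecular dimer energy of the probe with itself.
#' The duplex uses the RNA/DNA hybrid stack table for RNA targets and the
#' DNA/DNA table for cDNA targets; Tm is always the DNA-duplex melting
#' temperature of the probe.
#'
#' @param probe a [probe()] object (the probe must be the exact
#'   complement of the fragment's binding site).
#' @param fragment a [extract_fragment()] result.
#' @param target_chemistry `"DNA"` (cDNA targets) or `"RNA"`.
#' @param conditions a [thermo_conditions()] object.
#' @param maxloop interior-loop cap passed to the folding engine.
#' @param cache optional internal parameter cache (see
#'   [profile_probes()]).
#' @return object of class `energy_profile` with `dG_h`, `dG_p`, `dG_t`,
#'   `dG_pp`, `dG` (kcal/mol), `Tm` (°C), `probe_mfe` (kcal/mol).
#' @export
energy_profile <- function(probe, fragment,
                           target_chemistry = c("DNA", "RNA"),
                           conditions = thermo_conditions(),
                           maxloop = 15L, cache = NULL) {
  stopifnot(inherits(probe, "hyb_probe"), inherits(fragment, "target_fragment"))
  target_chemistry <- match.arg(target_chemistry)
  if (is.null(cache)) cache <- param_env()
  bs <- fragment$binding_site
  site_seq <- substr(fragment$seq, bs[1L] + 1L, bs[2L])
  expected <- revcomp(probe$seq, "DNA", target_chemistry)
  if (nchar(site_seq) != nchar(probe$seq) || site_seq != expected) {
    a <- strsplit(site_seq, "")[[1L]]; b <- strsplit(expected, "")[[1L]]
    pos <- if (length(a) != length(b)) 0L else which(a != b)[1L]
    stop("probe is not the exact complement of the binding site ",
         "(first mismatch at site position ", pos, ")", call. = FALSE)
  }
  duplex_type <- if (target_chemistry == "RNA") "RNA/DNA" else "DNA/DNA"
  p_dna <- cache$get("DNA/DNA")
  p_tgt <- if (target_chemistry == "RNA") cache$get("RNA/RNA") else p_dna
  p_dup <- cache$get(duplex_type)
  temp <- conditions$temperature

  dup <- duplex_thermo(probe$seq, duplex_type, conditions, params = p_dup)
  dG_h <- min(0, dup$dG_at_T)
  dG_p <- partition_function(probe$seq, p_dna, temp,
                             maxloop = maxloop)$ensemble_dG
  dG_t <- -opening_energy_cached(fragment$seq, bs, p_tgt, temp, maxloop,
                                 cache$folds)
  dG_pp <- dimer_energy(probe$seq, probe$seq, p_dna, temp, maxloop = maxloop)
  dup_dna <- if (duplex_type == "DNA/DNA") dup
             else duplex_thermo(probe$seq, "DNA/DNA", conditions,
                                params = p_dna)
  structure(list(probe_id = probe$id,
                 dG_h = dG_h, dG_p = dG_p, dG_t = dG_t, dG_pp = dG_pp,
                 dG = dG_h - dG_p - dG_t - dG_pp,
                 Tm = melting_temperature(dup_dna, conditions),
                 probe_mfe = mfe_structure(probe$seq, p_dna, temp,
                                           maxloop = maxloop)$mfe_dG,
                 target_chemistry = target_chemistry,
                 temperature = temp),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("energy profile for %s (%s target, %g degC):\n",
              x$probe_id, x$target_chemistry, x$temperature))
  cat(sprintf(
    "  dG_h=%.2f dG_p=%.2f dG_t=%.2f dG_pp=%.2f -> dG=%.2f kcal/mol\n",
    x$dG_h, x$dG_p, x$dG_t, x$dG_pp, x$dG))
  cat(sprintf("  Tm=%.2f degC, probe mfe=%.2f kcal/mol\n", x$Tm, x$probe_mfe))
  invisible(x)
}

#' Energy profiles for a probe set
#'
#' Maps probes to targets (unless a map is supplied), extracts flanked
#' fragments, and computes one [energy_profile()] row per uniquely mapped
#' probe.  Unconstrained fragment folds are cached, so probe sets tiling
#' short targets reuse the same fold.
#'
#' @param probes data frame (`probe_id`, `seq`) or list of [probe()]s.
#' @param targets named character vector of target sequences.
#' @param target_chemistry `"DNA"` or `"RNA"`.
#' @param conditions a [thermo_conditions()] object.
#' @param flank flank length for fragment extraction (default 200).
#' @param map optional precomputed [map_probes()] result.
#' @param maxloop interior-loop cap.
#' @return data frame with columns `probe_id`, `seq`, `target_id`,
#'   `site_start`, `site_end`, `dG_h`, `dG_p`, `dG_t`, `dG_pp`, `dG`,
#'   `Tm`, `mfe` (one row per mapped probe; coordinates 0-based
#'   half-open), with the map in attribute `"map"`.
#' @export
profile_probes <- function(probes, targets,
                           target_chemistry = c("DNA", "RNA"),
                           conditions = thermo_conditions(),
                           flank = 200L, map = NULL, maxloop = 15L) {
  target_chemistry <- match.arg(target_chemistry)
  probes <- as_probe_frame(probes)
  if (is.null(map)) map <- map_probes(probes, targets)
  stopifnot(inherits(map, "probe_target_map"))
  cache <- param_env()
  seqs <- probes$seq
  names(seqs) <- probes$probe_id
  ent <- map$entries
  rows <- vector("list", nrow(ent))
  for (r in seq_len(nrow(ent))) {
    pr <- probe(ent$probe_id[r], seqs[[ent$probe_id[r]]])
    frag <- extract_fragment(targets[[ent$target_id[r]]],
                             c(ent$start[r], ent$end[r]), flank,
                             target_id = ent$target_id[r])
    ep <- energy_profile(pr, frag, target_chemistry, conditions,
                         maxloop = maxloop, cache = cache)
    rows[[r]] <- data.frame(
      probe_id = pr$id, seq = pr$seq, target_id = ent$target_id[r],
      site_start = ent$start[r], site_end = ent$end[r],
      dG_h = ep$dG_h, dG_p = ep$dG_p, dG_t = ep$dG_t, dG_pp = ep$dG_pp,
      dG = ep$dG, Tm = ep$Tm, mfe = ep$probe_mfe,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(0), seq = character(0),
               target_id = character(0), site_start = integer(0),
               site_end = integer(0), dG_h = numeric(0), dG_p = numeric(0),
               dG_t = numeric(0), dG_pp = numeric(0), dG = numeric(0),
               Tm = numeric(0), mfe = numeric(0))
  attr(out, "map") <- map
  attr(out, "target_chemistry") <- target_chemistry
  out
}

#' Expressed-target filter
#'
#' Conservative expression call: the threshold is the mean intensity over
#' all mapped probes, and a target counts as expressed iff at least one
#' of its probes exceeds that mean.
#'
#' @param intensities data frame with columns `probe_id`, `intensity`.
#' @param map a [map_probes()] result.
#' @return character vector of expressed target ids, with the threshold
#'   in attribute `"threshold"`.
#' @export
expression_filter <- function(intensities, map) {
  stopifnot(is.data.frame(intensities),
            all(c("probe_id", "intensity") %in% names(intensities)),
            inherits(map, "probe_target_map"))
  ent <- map$entries
  m <- merge(ent[, c("probe_id", "target_id")], intensities, by = "probe_id")
  if (!nrow(m)) stop("no mapped probe has an intensity", call. = FALSE)
  threshold <- mean(m$intensity)
  mx <- tapply(m$intensity, m$target_id, max)
  expressed <- names(mx)[mx > threshold]
  structure(expressed, threshold = threshold)
}

#' Per-target intensity variation
#'
#' Probe-specific intensity variation per target, assayed as
#' `log2(max intensity / min intensity)` over the probes mapping to the
#' target, plus the grand mean over targets.  Targets with fewer than two
#' probes are dropped.
#'
#' @inheritParams expression_filter
#' @param targets optional restriction to a set of target ids (e.g. the
#'   expressed set).
#' @return list of class `variation_stats` with `per_target` (data frame
#'   `target_id`, `n_probes`, `log2_ratio`) and `mean_log2_ratio`.
#' @export
variation_stats <- function(intensities, map, targets = NULL) {
  stopifnot(is.data.frame(intensities),
            all(c("probe_id", "intensity") %in% names(intensities)),
            inherits(map, "probe_target_map"))
  if (any(intensities$intensity <= 0))
    stop("non-positive intensity", call. = FALSE)
  m <- merge(map$entries[, c("probe_id", "target_id")], intensities,
             by = "probe_id")
  if (!is.null(targets)) m <- m[m$target_id %in% targets, , drop = FALSE]
  sp <- split(m$intensity, m$target_id)
  sp <- sp[vapply(sp, length, integer(1)) >= 2L]
  if (!length(sp))
    stop("no target has >= 2 probes with intensities", call. = FALSE)
  per <- data.frame(target_id = names(sp),
                    n_probes = vapply(sp, length, integer(1)),
                    log2_ratio = vapply(sp, function(v) log2(max(v) / min(v)),
                                        numeric(1)),
                    row.names = NULL)
  structure(list(per_target = per,
                 mean_log2_ratio = mean(per$log2_ratio)),
            class = "variation_stats")
}

#' @export
print.variation_stats <- function(x, ...) {
  cat(sprintf(
    "probe intensity variation over %d targets: mean log2(max/min) = %.2f (%.1f-fold)\n",
    nrow(x$per_target), x$mean_log2_ratio, 2^x$mean_log2_ratio))
  invisible(x)
}
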