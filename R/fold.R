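#' @useDynLib hybtherm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# kcal/(K*mol); matches the 1.987 cal/(K*mol) used in the Tm equation.
R_KCAL <- 1.987e-3
T_REF <- 310.15  # K; reference temperature of the loop tables

.INF_E <- 1e9

base_codes <- function(seq) {
  chars <- strsplit(chartr("U", "T", seq), "", fixed = TRUE)[[1L]]
  match(chars, c("A", "C", "G", "T")) - 1L
}

# Loop penalty at loop size `sizes` (G37, Jacobson-Stockmayer beyond the table).
loop_G37 <- function(table, sizes) {
  lens <- as.integer(names(table))
  smax <- max(lens)
  out <- numeric(length(sizes))
  inside <- sizes %in% lens
  out[inside] <- table[as.character(sizes[inside])]
  big <- sizes > smax
  out[big] <- table[[as.character(smax)]] +
    1.75 * R_KCAL * T_REF * log(sizes[big] / smax)
  out[sizes < min(lens)] <- .INF_E
  out
}

# Evaluate all model tables at the working temperature for the C++ engine.
engine_tables <- function(params, temperature, n, maxloop) {
  t_k <- temperature + 273.15
  scale <- t_k / T_REF
  letters4 <- alphabet_letters(params$alphabet)
  stackG <- matrix(.INF_E, 4, 4)
  dH <- params$stacks$dH; dS <- params$stacks$dS
  names(dH) <- names(dS) <- params$stacks$stack
  for (a in 1:4) for (b in 1:4) {
    key <- paste0(letters4[a], letters4[b])
    stackG[a, b] <- dH[[key]] - t_k * dS[[key]] / 1000
  }
  pairG <- matrix(.INF_E, 4, 4)
  pairG[1, 4] <- pairG[4, 1] <- pairG[2, 3] <- pairG[3, 2] <- 0
  hair_sizes <- seq_len(max(3L, n))
  ml <- params$loops$multiloop * scale
  list(pairG = pairG,
       stackG = stackG,
       hairpinG = loop_G37(params$loops$hairpin, hair_sizes) * scale,
       bulgeG = loop_G37(params$loops$bulge, seq_len(maxloop)) * scale,
       internalG = loop_G37(params$loops$internal, seq_len(maxloop)) * scale,
       mla = ml[["a"]], mlb = ml[["b"]], mlc = ml[["c"]],
       RT = R_KCAL * t_k)
}

default_params_for <- function(seq) {
  if (grepl("U", toupper(seq), fixed = TRUE)) load_parameter_set("RNA/RNA")
  else load_parameter_set("DNA/DNA")
}

#' Partition function of a single strand
#'
#' Boltzmann-weighted sum over all pseudoknot-free secondary structures of
#' one strand under the loop-based nearest-neighbor model (Watson-Crick
#' pairs, minimum hairpin loop of 3 unpaired bases, interior loops capped
#' at `maxloop` unpaired bases in total).  The open chain contributes
#' weight 1, so `partition_Z >= 1` and the ensemble free energy
#' `-RT ln Z` is always `<= 0`.
#'
#' @param seq nucleotide string 5'→3' (DNA or RNA alphabet).
#' @param params an `nn_param_set`; defaults to `"DNA/DNA"` for DNA input
#'   and `"RNA/RNA"` when the sequence contains U.
#' @param temperature folding temperature in °C.
#' @param constrained optional logical vector (one element per base):
#'   `TRUE` bases are forbidden to pair.
#' @param maxloop interior-loop size cap (total unpaired bases).
#' @return object of class `fold_result` with `partition_Z`,
#'   `ensemble_dG` (kcal/mol), `temperature`, `parameter_set`.
#' @examples
#' partition_function("GGGGGAAAACCCCC")$ensemble_dG
#' partition_function("AAAAAAAAAA")$partition_Z  # 1: nothing can pair
#' @export
partition_function <- function(seq, params = NULL, temperature = 37,
                               constrained = NULL, maxloop = 15L) {
  if (is.null(params)) params <- default_params_for(seq)
  s <- check_seq(seq, params$alphabet)
  n <- nchar(s)
  if (is.null(constrained)) constrained <- rep(FALSE, n)
  stopifnot(length(constrained) == n)
  tb <- engine_tables(params, temperature, n, maxloop)
  lnZ <- fold_partition_cpp(base_codes(s), constrained, tb$pairG, tb$stackG,
                            tb$hairpinG, tb$bulgeG, tb$internalG,
                            tb$mla, tb$mlb, tb$mlc, tb$RT, as.integer(maxloop))
  structure(list(partition_Z = exp(lnZ),
                 ln_Z = lnZ,
                 ensemble_dG = -tb$RT * lnZ,
                 temperature = temperature,
                 parameter_set = params$name),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("Fold ensemble (%s, %g degC): Z = %.6g, dG = %.3f kcal/mol\n",
              x$parameter_set, x$temperature, x$partition_Z, x$ensemble_dG))
  invisible(x)
}

#' Minimum free energy structure
#'
#' Most stable pseudoknot-free secondary structure of one strand under the
#' same energy model as [partition_function()].  When no structure is
#' stable the open chain (all dots, energy 0) is returned.
#'
#' @inheritParams partition_function
#' @return object of class `mfe_result` with `structure` (dot-bracket)
#'   and `mfe_dG` (kcal/mol, `<= 0`).
#' @examples
#' mfe_structure("GGGGGGAAAACCCCCC")$structure
#' @export
mfe_structure <- function(seq, params = NULL, temperature = 37,
                          maxloop = 15L) {
  if (is.null(params)) params <- default_params_for(seq)
  s <- check_seq(seq, params$alphabet)
  n <- nchar(s)
  tb <- engine_tables(params, temperature, n, maxloop)
  res <- fold_mfe_cpp(base_codes(s), rep(FALSE, n), tb$pairG, tb$stackG,
                      tb$hairpinG, tb$bulgeG, tb$internalG,
                      tb$mla, tb$mlb, tb$mlc, tb$RT, as.integer(maxloop))
  structure(list(structure = res$structure,
                 mfe_dG = res$mfe,
                 temperature = temperature,
                 parameter_set = params$name),
            class = "mfe_result")
}

#' @export
print.mfe_result <- function(x, ...) {
  cat(sprintf("mfe = %.3f kcal/mol (%s, %g degC)\n%s\n",
              x$mfe_dG, x$parameter_set, x$temperature, x$structure))
  invisible(x)
}

#' Opening (accessibility) energy of a region
#'
#' Free-energy cost of keeping a region of a folded strand completely
#' unpaired: `-RT ln P(region unpaired)` with
#' `P = Z_constrained / Z`.  Always `>= 0`; zero for strands that cannot
#' fold.  When the region is the whole strand this equals
#' `-ensemble_dG` exactly.
#'
#' @inheritParams partition_function
#' @param region integer pair `c(start, end)`, 0-based half-open, within
#'   the strand.
#' @return opening energy in kcal/mol (numeric, `>= 0`).
#' @examples
#' opening_energy("GGGGGAAAACCCCC", c(5, 9))
#' @export
opening_energy <- function(seq, region, params = NULL, temperature = 37,
                           maxloop = 15L) {
  if (is.null(params)) params <- default_params_for(seq)
  s <- check_seq(seq, params$alphabet)
  n <- nchar(s)
  region <- as.integer(region)
  if (length(region) != 2L || region[1L] < 0L || region[2L] > n ||
      region[1L] >= region[2L])
    stop("region [", region[1L], ",", region[2L],
         ") out of bounds for strand of length ", n, call. = FALSE)
  blocked <- rep(FALSE, n)
  blocked[(region[1L] + 1L):region[2L]] <- TRUE
  tb <- engine_tables(params, temperature, n, maxloop)
  codes <- base_codes(s)
  lnZ <- fold_partition_cpp(codes, rep(FALSE, n), tb$pairG, tb$stackG,
                            tb$hairpinG, tb$bulgeG, tb$internalG,
                            tb$mla, tb$mlb, tb$mlc, tb$RT, as.integer(maxloop))
  lnZc <- fold_partition_cpp(codes, blocked, tb$pairG, tb$stackG,
                             tb$hairpinG, tb$bulgeG, tb$internalG,
                             tb$mla, tb$mlb, tb$mlc, tb$RT, as.integer(maxloop))
  max(0, tb$RT * (lnZ - lnZc))
}

#' Intermolecular dimer energy
#'
#' Ensemble free energy of the purely intermolecular pairings between two
#' otherwise unstructured strands (the probe-probe dimer term of the
#' hybridization model).  The interaction partition function sums
#' Boltzmann weights over all antiparallel, non-crossing sets of
#' intermolecular Watson-Crick pairs, with stacking between adjacent
#' pairs, bulge/internal penalties between separated pairs, a per-duplex
#' initiation term, and the open (unbound) state at weight 1 — so the
#' returned energy is `<= 0`, and exactly 0 when no pair can form.
#'
#' @param seqA,seqB the two strands, 5'→3'.  For the `"RNA/DNA"` set
#'   `seqA` must be the RNA strand.
#' @inheritParams partition_function
#' @return dimer free energy in kcal/mol (`<= 0`).
#' @examples
#' dimer_energy("AAAAA", "AAAAA")           # 0: no A.A pairs
#' dimer_energy("ACGTACGT", revcomp("ACGTACGT"))
#' @export
dimer_energy <- function(seqA, seqB, params = NULL, temperature = 37,
                         maxloop = 15L) {
  if (is.null(params)) params <- default_params_for(seqA)
  alphaA <- params$alphabet
  alphaB <- if (params$name == "RNA/DNA") "DNA" else params$alphabet
  sA <- check_seq(seqA, alphaA, "seqA")
  sB <- check_seq(seqB, alphaB, "seqB")
  tb <- engine_tables(params, temperature, max(nchar(sA), nchar(sB)), maxloop)
  t_k <- temperature + 273.15
  initG <- params$init[["dH"]] - t_k * params$init[["dS"]] / 1000
  lnZ <- dimer_partition_cpp(base_codes(sA), base_codes(sB), tb$pairG,
                             tb$stackG, tb$bulgeG, tb$internalG,
                             initG, tb$RT, as.integer(maxloop))
  min(0, -tb$RT * lnZ)
}

# Internal: opening energy with a memo for the unconstrained fold, so many
# binding sites on the same fragment pay for one full fold only.
opening_energy_cached <- function(seq, region, params, temperature,
                                  maxloop, memo) {
  n <- nchar(seq)
  tb <- engine_tables(params, temperature, n, maxloop)
  codes <- base_codes(seq)
  key <- paste0(params$name, "|", temperature, "|", seq)
  lnZ <- memo[[key]]
  if (is.null(lnZ)) {
    lnZ <- fold_partition_cpp(codes, rep(FALSE, n), tb$pairG, tb$stackG,
                              tb$hairpinG, tb$bulgeG, tb$internalG,
                              tb$mla, tb$mlb, tb$mlc, tb$RT,
                              as.integer(maxloop))
    memo[[key]] <- lnZ
  }
  blocked <- rep(FALSE, n)
  blocked[(region[1L] + 1L):region[2L]] <- TRUE
  lnZc <- fold_partition_cpp(codes, blocked, tb$pairG, tb$stackG,
                             tb$hairpinG, tb$bulgeG, tb$internalG,
                             tb$mla, tb$mlb, tb$mlc, tb$RT,
                             as.integer(maxloop))
  max(0, tb$RT * (lnZ - lnZc))
}

# ---------------------------------------------------------------------------
# Pure-R oracle: exhaustive structure enumeration and loop-decomposition
# scoring, independent of the C++ dynamic programs.

dotbracket_pairs <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") open <- c(open, i)
    else if (chars[i] == ")") {
      if (!length(open)) stop("unbalanced structure", call. = FALSE)
      pairs <- rbind(pairs, c(open[length(open)], i))
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced structure", call. = FALSE)
  pairs
}

#' Score a secondary structure
#'
#' Free energy of a single explicit structure under the package's loop
#' decomposition, computed in plain R by walking the loops (hairpin,
#' stack, bulge, internal, multiloop, free exterior).  Serves as the
#' independent re-scoring oracle for the dynamic-programming engine.
#'
#' @inheritParams partition_function
#' @param structure dot-bracket string, same length as `seq`.
#' @return free energy in kcal/mol; `Inf` for structures outside the
#'   model (interior loop above `maxloop`).
#' @examples
#' score_structure("GGGGGGAAAACCCCCC", "((((((....))))))")
#' @export
score_structure <- function(seq, structure, params = NULL, temperature = 37,
                            maxloop = 15L) {
  if (is.null(params)) params <- default_params_for(seq)
  s <- check_seq(seq, params$alphabet)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  stopifnot(nchar(structure) == n)
  pairs <- dotbracket_pairs(structure)
  if (!nrow(pairs)) return(0)
  if (any(!wc_pair(chars[pairs[, 1]], chars[pairs[, 2]])))
    stop("structure contains a non-Watson-Crick pair", call. = FALSE)
  if (any(pairs[, 2] - pairs[, 1] - 1 < 3))
    stop("structure violates the minimum hairpin loop of 3", call. = FALSE)
  t_k <- temperature + 273.15
  scale <- t_k / T_REF
  dH <- params$stacks$dH; dS <- params$stacks$dS
  names(dH) <- names(dS) <- params$stacks$stack
  stack_G <- function(i) {
    key <- paste0(chars[i], chars[i + 1])
    dH[[key]] - t_k * dS[[key]] / 1000
  }
  ml <- params$loops$multiloop * scale
  loop_at <- function(table, size) {
    g <- loop_G37(table, size) * scale
    g
  }
  total <- 0
  ord <- order(pairs[, 1])
  pairs <- pairs[ord, , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    # directly enclosed pairs: inside (i, j) and not inside a deeper pair
    ins <- pairs[pairs[, 1] > i & pairs[, 2] < j, , drop = FALSE]
    if (nrow(ins)) {
      top <- rep(TRUE, nrow(ins))
      for (q in seq_len(nrow(ins)))
        top[q] <- !any(ins[, 1] < ins[q, 1] & ins[, 2] > ins[q, 2])
      ins <- ins[top, , drop = FALSE]
    }
    if (nrow(ins) == 0L) {
      total <- total + loop_at(params$loops$hairpin, j - i - 1)
    } else if (nrow(ins) == 1L) {
      k <- ins[1, 1]; l <- ins[1, 2]
      g1 <- k - i - 1; g2 <- j - l - 1
      if (g1 == 0 && g2 == 0) total <- total + stack_G(i)
      else if (g1 + g2 > maxloop) return(Inf)
      else if (g1 == 0 || g2 == 0)
        total <- total + loop_at(params$loops$bulge, g1 + g2)
      else total <- total + loop_at(params$loops$internal, g1 + g2)
    } else {
      unpaired <- (j - i - 1) - sum(ins[, 2] - ins[, 1] + 1)
      total <- total + ml[["a"]] + ml[["b"]] * (nrow(ins) + 1) +
        ml[["c"]] * unpaired
    }
  }
  total
}

#' Exhaustive structure enumeration (verification oracle)
#'
#' Enumerates every pseudoknot-free secondary structure of a short strand
#' (Watson-Crick pairs, hairpin loops >= 3) and scores each with
#' [score_structure()].  Deterministic order.  Intended as the brute-force
#' oracle against which the dynamic-programming engine is validated;
#' refuses strands longer than `limit` (exponential blow-up).
#'
#' @inheritParams partition_function
#' @param limit hard length cap (default 20).
#' @return data frame with columns `structure`, `energy`; structures with
#'   interior loops above `maxloop` (outside the engine's model) are
#'   dropped.
#' @examples
#' enumerate_structures("GGGAAAACCC")
#' @export
enumerate_structures <- function(seq, params = NULL, temperature = 37,
                                 maxloop = 15L, limit = 20L) {
  if (is.null(params)) params <- default_params_for(seq)
  s <- check_seq(seq, params$alphabet)
  n <- nchar(s)
  if (n > limit)
    stop("enumerate_structures refuses length ", n, " > limit ", limit,
         " (exponential enumeration)", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  enum <- function(i, j) {
    if (j - i < 4L) return(list(matrix(integer(0), ncol = 2)))
    out <- list()
    for (str_rest in enum(i + 1L, j)) out[[length(out) + 1L]] <- str_rest
    for (k in seq.int(i + 4L, j)) {
      if (!wc_pair(chars[i], chars[k])) next
      inner <- enum(i + 1L, k - 1L)
      outer <- enum(k + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
    }
    out
  }
  structs <- enum(1L, n)
  db <- vapply(structs, function(p) {
    x <- rep(".", n)
    if (nrow(p)) { x[p[, 1]] <- "("; x[p[, 2]] <- ")" }
    paste(x, collapse = "")
  }, character(1))
  energy <- vapply(db, score_structure, numeric(1), seq = s, params = params,
                   temperature = temperature, maxloop = maxloop,
                   USE.NAMES = FALSE)
  keep <- is.finite(energy)
  data.frame(structure = db[keep], energy = energy[keep],
             stringsAsFactors = FALSE)
}

# Brute-force intermolecular dimer oracle (R, independent of the C++ DP).
enumerate_dimer_energy <- function(seqA, seqB, params = NULL,
                                   temperature = 37, maxloop = 15L,
                                   limit = 12L) {
  if (is.null(params)) params <- default_params_for(seqA)
  alphaA <- params$alphabet
  alphaB <- if (params$name == "RNA/DNA") "DNA" else params$alphabet
  sA <- check_seq(seqA, alphaA); sB <- check_seq(seqB, alphaB)
  na <- nchar(sA); nb <- nchar(sB)
  if (na > limit || nb > limit)
    stop("dimer enumeration limited to ", limit, " nt per strand",
         call. = FALSE)
  a <- strsplit(sA, "", fixed = TRUE)[[1L]]
  b <- strsplit(sB, "", fixed = TRUE)[[1L]]
  t_k <- temperature + 273.15
  RT <- R_KCAL * t_k
  scale <- t_k / T_REF
  dH <- params$stacks$dH; dS <- params$stacks$dS
  names(dH) <- names(dS) <- params$stacks$stack
  initG <- params$init[["dH"]] - t_k * params$init[["dS"]] / 1000
  # recursively extend ordered pair lists: i ascending, j descending
  Z <- 0
  extend <- function(pl) {
    # pl: matrix of pairs so far (ordered); score and recurse
    last <- pl[nrow(pl), ]
    e <- score_pl(pl)
    if (is.finite(e)) Z <<- Z + exp(-e / RT)
    if (last[1] < na && last[2] > 1) {
      for (i in seq.int(last[1] + 1L, na)) for (j in seq_len(last[2] - 1L)) {
        if (wc_pair(a[i], b[j])) extend(rbind(pl, c(i, j)))
      }
    }
  }
  score_pl <- function(pl) {
    e <- initG
    if (nrow(pl) > 1) for (r in 2:nrow(pl)) {
      g1 <- pl[r, 1] - pl[r - 1, 1] - 1
      g2 <- pl[r - 1, 2] - pl[r, 2] - 1
      if (g1 == 0 && g2 == 0) {
        key <- paste0(a[pl[r - 1, 1]], a[pl[r, 1]])
        e <- e + dH[[key]] - t_k * dS[[key]] / 1000
      } else if (g1 + g2 > maxloop) return(Inf)
      else if (g1 == 0 || g2 == 0)
        e <- e + loop_G37(params$loops$bulge, g1 + g2) * scale
      else e <- e + loop_G37(params$loops$internal, g1 + g2) * scale
    }
    e
  }
  for (i in seq_len(na)) for (j in seq_len(nb))
    if (wc_pair(a[i], b[j])) extend(matrix(c(i, j), ncol = 2))
  min(0, -RT * log1p(Z))
}
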