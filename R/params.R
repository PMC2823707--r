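#' Nearest-neighbor parameter sets
#'
#' Loads one of the packaged nearest-neighbor parameter sets.  Each set
#' bundles the dinucleotide stack table (enthalpy/entropy), a duplex
#' initiation term and the shared loop-penalty tables used by the folding
#' engine.  Three duplex chemistries are supported:
#'
#' * `"DNA/DNA"` — DNA self-structure, probe-probe dimers and DNA duplexes
#'   (unified oligonucleotide nearest-neighbor set);
#' * `"RNA/RNA"` — RNA self-structure (Watson-Crick RNA stacks);
#' * `"RNA/DNA"` — hybrid probe-target duplexes, keyed by the RNA strand
#'   dinucleotide 5'→3' (orientation specific, non-symmetric).
#'
#' Tables ship as plain whitespace-delimited text under
#' `inst/extdata/params/` (one stack per line: key, dH in kcal/mol, dS in
#' cal/(K·mol); `#` comments) so they can be inspected and round-tripped
#' losslessly.
#'
#' @param name one of `"DNA/DNA"`, `"RNA/RNA"`, `"RNA/DNA"`.
#' @return an object of class `nn_param_set`: a list with elements `name`,
#'   `stacks` (data frame with `stack`, `dH`, `dS`), `init` (named numeric
#'   `dH`, `dS`), `loops` (hairpin/bulge/internal penalty vectors and
#'   multiloop coefficients `a`, `b`, `c` at the 310.15 K reference),
#'   `alphabet` (`"DNA"` or `"RNA"`; the self-folding alphabet of the set)
#'   and `reference`.
#' @examples
#' ps <- load_parameter_set("DNA/DNA")
#' nrow(ps$stacks)  # 16 dinucleotide stacks
#' @export
load_parameter_set <- function(name) {
  files <- c("DNA/DNA" = "stack_dna_dna.tsv",
             "RNA/RNA" = "stack_rna_rna.tsv",
             "RNA/DNA" = "stack_rna_dna.tsv")
  if (!is.character(name) || length(name) != 1L || !name %in% names(files))
    stop("unknown parameter set '", paste(name, collapse = ","),
         "'; supported: ", paste(names(files), collapse = ", "),
         call. = FALSE)
  path <- system.file("extdata", "params", files[[name]],
                      package = "hybtherm", mustWork = TRUE)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("stack", "dH", "dS"),
                           colClasses = c("character", "numeric", "numeric"),
                           stringsAsFactors = FALSE)
  init_row <- tab$stack == "init"
  if (sum(init_row) != 1L)
    stop("malformed parameter table '", files[[name]],
         "': missing 'init' entry", call. = FALSE)
  init <- c(dH = tab$dH[init_row], dS = tab$dS[init_row])
  stacks <- tab[!init_row, , drop = FALSE]
  rownames(stacks) <- NULL

  alphabet <- if (name == "DNA/DNA") "DNA" else "RNA"
  letters4 <- alphabet_letters(alphabet)
  wanted <- as.vector(outer(letters4, letters4, paste0))
  missing <- setdiff(wanted, stacks$stack)
  if (length(missing))
    stop("malformed parameter table '", files[[name]], "': missing stack ",
         missing[[1L]], call. = FALSE)
  if (anyDuplicated(stacks$stack))
    stop("malformed parameter table '", files[[name]], "': duplicate stack ",
         stacks$stack[duplicated(stacks$stack)][1L], call. = FALSE)

  refs <- c("DNA/DNA" = "SantaLucia unified DNA nearest-neighbor parameters",
            "RNA/RNA" = "Xia et al. Watson-Crick RNA nearest-neighbor parameters",
            "RNA/DNA" = "Sugimoto et al. RNA/DNA hybrid nearest-neighbor parameters")
  structure(list(name = name,
                 stacks = stacks,
                 init = init,
                 loops = load_loop_tables(),
                 alphabet = alphabet,
                 reference = refs[[name]]),
            class = "nn_param_set")
}

# Shared loop-penalty tables (G37, kcal/mol); validated non-negative.
load_loop_tables <- function() {
  path <- system.file("extdata", "params", "loops.tsv",
                      package = "hybtherm", mustWork = TRUE)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("type", "key", "G37"),
                           colClasses = c("character", "character", "numeric"),
                           stringsAsFactors = FALSE)
  pick <- function(type) {
    rows <- tab[tab$type == type, , drop = FALSE]
    v <- rows$G37
    names(v) <- rows$key
    v
  }
  hairpin <- pick("hairpin"); bulge <- pick("bulge"); internal <- pick("internal")
  ml <- pick("multiloop")
  if (any(c(hairpin, bulge, internal) < 0))
    stop("malformed loop table: negative loop penalty", call. = FALSE)
  if (!all(c("a", "b", "c") %in% names(ml)))
    stop("malformed loop table: incomplete multiloop coefficients",
         call. = FALSE)
  list(hairpin = hairpin, bulge = bulge, internal = internal, multiloop = ml)
}

#' @export
print.nn_param_set <- function(x, ...) {
  cat("Nearest-neighbor parameter set: ", x$name, "\n", sep = "")
  cat("  ", nrow(x$stacks), " stacks; init dH=", x$init[["dH"]],
      " kcal/mol, dS=", x$init[["dS"]], " cal/(K*mol)\n", sep = "")
  cat("  reference: ", x$reference, "\n", sep = "")
  invisible(x)
}

alphabet_letters <- function(alphabet) {
  switch(alphabet,
         DNA = c("A", "C", "G", "T"),
         RNA = c("A", "C", "G", "U"),
         stop("unknown alphabet '", alphabet, "'", call. = FALSE))
}

# Validate and normalise a nucleotide string for a given alphabet.
check_seq <- function(seq, alphabet, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  s <- toupper(seq)
  letters4 <- alphabet_letters(alphabet)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% letters4)
  if (length(bad))
    stop(what, " contains invalid ", alphabet, " character '",
         chars[bad[1L]], "' at position ", bad[1L], call. = FALSE)
  s
}

#' Reverse complement
#'
#' Reverse complement of a nucleotide string.  `to` selects the output
#' alphabet, so a DNA probe can be turned directly into its implied RNA
#' target site (and vice versa).
#'
#' @param seq nucleotide string, 5'→3'.
#' @param from,to `"DNA"` or `"RNA"`.
#' @return the reverse complement, 5'→3', in the `to` alphabet.
#' @examples
#' revcomp("ACGT")             # "ACGT"
#' revcomp("ACGT", to = "RNA") # "ACGU"
#' @export
revcomp <- function(seq, from = "DNA", to = from) {
  s <- check_seq(seq, from)
  comp <- chartr("ACGTU", "TGCAA", s)
  if (to == "RNA") comp <- chartr("T", "U", comp)
  if (to == "DNA") comp <- chartr("U", "T", comp)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Watson-Crick partner test used everywhere (no wobble pairs).
wc_pair <- function(a, b) {
  (a == "A" & (b == "T" | b == "U")) |
    ((a == "T" | a == "U") & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}
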