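# Monoisotopic atomic masses (IUPAC). D = deuterium, its own symbol so that
# NaBD4-labelled products can be tracked element-wise.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.9720706900,
  D = 2.0141017780
)

#' Proton mass used for m/z conversions
#'
#' Charge is modelled as protonation: m/z = (M + z * proton) / z with
#' proton = 1.007276 Da (electron-corrected). Exported so that reports and
#' external checks can reproduce every m/z exactly.
#' @export
PROTON_MASS <- 1.007276466

.KNOWN_ELEMENTS <- names(.ATOMIC_MASS)

#' Construct a molecular formula
#'
#' A molecular formula is a named integer vector of element counts over the
#' alphabet C, H, N, O, S, D (D = deuterium). All arithmetic on formulas is
#' element-wise; subtraction that would drive any count negative is an error,
#' so a formula can never leave the valid (non-negative) space.
#'
#' @param counts named numeric vector or list, element symbol -> count.
#' @return object of class `molform`.
#' @examples
#' molform(c(H = 2, O = 1))
#' @export
molform <- function(counts = numeric()) {
  counts <- unlist(counts)
  if (length(counts)) {
    bad <- setdiff(names(counts), .KNOWN_ELEMENTS)
    if (length(bad)) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    }
    if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
      stop("element counts must be non-negative integers")
    }
  }
  full <- stats::setNames(integer(length(.KNOWN_ELEMENTS)), .KNOWN_ELEMENTS)
  full[names(counts)] <- as.integer(round(counts))
  structure(full, class = "molform")
}

#' Parse a Hill-style molecular formula string
#'
#' Accepts strings such as `"H2O"`, `"CH2"` or `"C57H71N13O15S2"`; a missing
#' count defaults to 1. Round-trips through [format_formula()].
#'
#' @param text formula string.
#' @return `molform` object.
#' @examples
#' parse_formula("C57H71N13O15S2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string")
  }
  if (text == "") {
    return(molform())
  }
  # element token: one uppercase letter + optional lowercase, optional digits
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (!length(tokens) || paste(tokens, collapse = "") != text) {
    offending <- substr(text, 1, 8)
    stop("malformed formula string near '", offending, "'")
  }
  counts <- stats::setNames(integer(0), character(0))
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% .KNOWN_ELEMENTS) {
      stop("unknown element symbol '", el, "' in formula '", text, "'")
    }
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  molform(counts)
}

#' Write a formula in canonical Hill order
#'
#' Hill convention: C first, then H, then remaining elements alphabetically
#' (D, N, O, S). Elements with zero count are omitted; a count of one is
#' written without a digit.
#'
#' @param f `molform`.
#' @return character scalar.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "molform"))
  ord <- c("C", "H", sort(setdiff(.KNOWN_ELEMENTS, c("C", "H"))))
  parts <- vapply(ord, function(el) {
    n <- f[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste(parts, collapse = "")
}

#' @export
print.molform <- function(x, ...) {
  cat("<molform> ", format_formula(x), "  (",
      sprintf("%.4f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' @export
`+.molform` <- function(e1, e2) {
  stopifnot(inherits(e1, "molform"), inherits(e2, "molform"))
  molform(unclass(e1) + unclass(e2))
}

#' @export
`-.molform` <- function(e1, e2) {
  stopifnot(inherits(e1, "molform"), inherits(e2, "molform"))
  out <- unclass(e1) - unclass(e2)
  if (any(out < 0)) {
    neg <- names(out)[out < 0]
    stop("infeasible formula subtraction: negative count for ",
         paste(neg, collapse = ", "))
  }
  molform(out)
}

#' @export
`==.molform` <- function(e1, e2) {
  all(unclass(e1) == unclass(e2))
}

#' Multiply a formula by a non-negative integer
#' @param f `molform`.
#' @param n non-negative integer.
#' @export
formula_times <- function(f, n) {
  stopifnot(inherits(f, "molform"), n >= 0, n == round(n))
  molform(unclass(f) * as.integer(n))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count x monoisotopic atomic mass over the internal IUPAC table
#' (C 12, H 1.0078250, N 14.0030740, O 15.9949146, S 31.9720707,
#' D 2.0141018). Deterministic to well below 1e-6 Da.
#'
#' @param f `molform`.
#' @return mass in Da (numeric scalar).
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))  # 18.0106
#' @export
monoisotopic_mass <- function(f) {
  stopifnot(inherits(f, "molform"))
  sum(unclass(f) * .ATOMIC_MASS[names(unclass(f))])
}

# ---- residue table -----------------------------------------------------

.residue_table_build <- function() {
  tab <- list(
    G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
    V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
    I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
    K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
    F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O",
    # dehydrated / ring-derived states:
    Dha = "C3H3NO",    # Ser - H2O (dehydroalanine)
    Dhb = "C4H5NO",    # Thr - H2O (dehydrobutyrine)
    Abu = "C4H7NO",    # 2-aminobutyric acid (Thr-derived after ring opening)
    AlaD = "C3H4DNO",  # Ala with one deuterium (NaBD4 reduction product)
    AbuD = "C4H6DNO"   # Abu with one deuterium
  )
  lapply(tab, parse_formula)
}

.RESIDUES <- .residue_table_build()

#' Residue formula table
#'
#' Internal-residue formulas (amino acid minus H2O) for the 20 standard
#' residues plus the derived states used by lanthipeptide chemistry:
#' Dha (dehydroalanine, Ser - H2O), Dhb (dehydrobutyrine, Thr - H2O),
#' Abu (2-aminobutyric acid), and singly deuterated Ala/Abu variants for
#' NaBD4 reduction products. The table is immutable.
#'
#' @return named list of `molform` objects.
#' @export
residue_table <- function() .RESIDUES

#' Neutral molecular formula of a linear peptide
#'
#' Sum of internal residue formulas plus one H2O for the free N/C termini.
#'
#' @param sequence character scalar of residue letters.
#' @param table residue table, by default [residue_table()].
#' @return `molform`.
#' @examples
#' format_formula(peptide_formula("GCGFTCSPFSSW"))  # "C57H75N13O17S2"
#' @export
peptide_formula <- function(sequence, table = residue_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  letters_vec <- strsplit(sequence, "")[[1]]
  unknown <- which(!letters_vec %in% names(table))
  if (length(unknown)) {
    stop("unknown residue '", letters_vec[unknown[1]],
         "' at position ", unknown[1])
  }
  out <- parse_formula("H2O")
  for (aa in letters_vec) out <- out + table[[aa]]
  out
}

# ---- modification sets -------------------------------------------------

#' Construct a set of anticipated post-translational modifications
#'
#' The modification classes considered when linking predicted core peptides
#' to MS1 signals: dehydration (-H2O each, on Ser/Thr), methylation
#' (+CH2 each), and dehydrogenation (-H2 each, e.g. a disulfide crosslink).
#' Arbitrary extra deltas can be supplied as named `add`/`remove` formulas.
#'
#' @param n_dehydration,n_methylation,n_dehydrogenation non-negative counts.
#' @param extra list of extra deltas, each a list with fields `name` and at
#'   least one of `add`, `remove` (each a `molform`).
#' @return object of class `modset`.
#' @export
modification_set <- function(n_dehydration = 0L, n_methylation = 0L,
                             n_dehydrogenation = 0L, extra = list()) {
  stopifnot(n_dehydration >= 0, n_methylation >= 0, n_dehydrogenation >= 0)
  for (e in extra) {
    if (is.null(e$name) || (is.null(e$add) && is.null(e$remove))) {
      stop("each extra delta needs a name and an add and/or remove formula")
    }
  }
  structure(list(
    n_dehydration = as.integer(n_dehydration),
    n_methylation = as.integer(n_methylation),
    n_dehydrogenation = as.integer(n_dehydrogenation),
    extra = extra
  ), class = "modset")
}

#' @export
print.modset <- function(x, ...) {
  cat("<modset> -", x$n_dehydration, "H2O, +", x$n_methylation, "CH2, -",
      x$n_dehydrogenation, "H2",
      if (length(x$extra)) paste0(", +", length(x$extra), " extra") else "",
      "\n", sep = "")
  invisible(x)
}

#' Total number of modifications in a set
#' @param mods `modset`.
#' @export
n_modifications <- function(mods) {
  mods$n_dehydration + mods$n_methylation + mods$n_dehydrogenation +
    length(mods$extra)
}

#' Apply a modification set to a neutral formula
#'
#' Element-wise: -n_dehydration x H2O, +n_methylation x CH2,
#' -n_dehydrogenation x H2, then each extra delta. Fully invertible via
#' `revert = TRUE`; applying then reverting is the identity.
#'
#' @param f `molform` of the unmodified species.
#' @param mods `modset`.
#' @param revert if TRUE undo the set instead of applying it.
#' @return modified `molform`.
#' @export
apply_modifications <- function(f, mods, revert = FALSE) {
  stopifnot(inherits(f, "molform"), inherits(mods, "modset"))
  h2o <- parse_formula("H2O"); ch2 <- parse_formula("CH2")
  h2 <- parse_formula("H2")
  plus <- formula_times(ch2, mods$n_methylation)
  minus <- formula_times(h2o, mods$n_dehydration) +
    formula_times(h2, mods$n_dehydrogenation)
  for (e in mods$extra) {
    if (!is.null(e$add)) plus <- plus + e$add
    if (!is.null(e$remove)) minus <- minus + e$remove
  }
  if (revert) {
    f + minus - plus
  } else {
    out <- tryCatch(f + plus - minus, error = function(err) {
      stop("infeasible modification set for ", format_formula(f), ": ",
           conditionMessage(err))
    })
    out
  }
}

#' Net mass delta of a modification set
#' @param mods `modset`.
#' @return signed mass change in Da.
#' @export
modification_delta_mass <- function(mods) {
  base <- apply_modifications(parse_formula("C100H200N50O50S10"), mods)
  monoisotopic_mass(base) - monoisotopic_mass(parse_formula("C100H200N50O50S10"))
}

# ---- m/z arithmetic ----------------------------------------------------

#' m/z of a neutral mass at charge z
#'
#' m/z = (M + z * proton) / z with proton mass `PROTON_MASS` (protonation
#' convention, electron-corrected).
#'
#' @param mass neutral monoisotopic mass in Da.
#' @param z positive integer charge.
#' @export
mz_from_neutral <- function(mass, z) {
  if (any(z < 1) || any(z != round(z))) stop("charge z must be a positive integer")
  (mass + z * PROTON_MASS) / z
}

#' Neutral mass from an observed m/z at charge z
#'
#' Exact inverse of [mz_from_neutral()].
#'
#' @param mz observed m/z.
#' @param z positive integer charge.
#' @export
neutral_from_mz <- function(mz, z) {
  if (any(z < 1) || any(z != round(z))) stop("charge z must be a positive integer")
  mz * z - z * PROTON_MASS
}

#' Signed ppm error of an observed m/z against a theoretical m/z
#'
#' 1e6 * (observed - theoretical) / theoretical. Positive means the observed
#' value is heavier than theory.
#'
#' @param observed,theoretical m/z values; `theoretical` must be > 0.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Nominal (integer) mass of a formula
#'
#' Rounded monoisotopic mass; used for the -34/+16 Da ring-fragmentation
#' bookkeeping only.
#' @param f `molform`.
#' @export
nominal_mass <- function(f) as.integer(round(monoisotopic_mass(f)))
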