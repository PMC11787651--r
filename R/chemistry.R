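# Monoisotopic atomic masses (IUPAC), Da.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

.PROTON_MASS <- 1.007276466
.WATER_MASS <- 2 * 1.0078250319 + 15.9949146221
.NEUTRON_SPACING <- 1.0033548378 # 13C - 12C, used for isotope peak spacing

# Isotope mass/abundance tables per element, ordered by increasing mass.
# Columns: mass (Da), abundance (fraction).
.ISOTOPES <- list(
  C = cbind(mass = c(12.0, 13.0033548378), ab = c(0.9893, 0.0107)),
  H = cbind(mass = c(1.0078250319, 2.0141017780), ab = c(0.999885, 0.000115)),
  N = cbind(mass = c(14.0030740052, 15.0001088984), ab = c(0.99636, 0.00364)),
  O = cbind(mass = c(15.9949146221, 16.9991315, 17.9991604),
            ab = c(0.99757, 0.00038, 0.00205)),
  S = cbind(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
            ab = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = cbind(mass = c(30.97376151), ab = c(1.0))
)

# Residue elemental compositions (residue = amino acid - H2O).
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2", P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS", L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3", Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS", H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2", W = "C11H10N2O"
)

#' Parse an elemental formula string
#'
#' Accepts simple Hill-style formulas over C, H, N, O, S, P such as
#' \code{"C3H4O"} or \code{"HPO3"}.
#'
#' @param formula a single formula string.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  counts <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]+$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.ATOMIC_MASS))
      stop("unknown element '", el, "' in formula ", formula)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

# Add two composition vectors (named counts).
.comp_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- integer(length(els)); names(out) <- els
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition named count vector (as from [parse_formula()]) or a
#'   formula string.
#' @return mass in Da.
#' @export
formula_mass <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  sum(.ATOMIC_MASS[names(composition)] * composition)
}

# ---- Modification registry ---------------------------------------------------

#' Default modification registry
#'
#' Short-code PTMs and the propionyl derivatization group, each with its
#' target residues and elemental composition. The trimethyl/acetyl pair is
#' pseudo-isobaric (42.047 vs 42.011 Da) and drives the tight MS1 tolerance
#' used throughout. \code{Kacme} (methyl + acetyl on one lysine) shares the
#' composition of the propionyl group.
#'
#' @return data.frame with columns name, targets, formula, delta.
#' @export
default_modifications <- function() {
  reg <- data.frame(
    name    = c("ac",    "me1",  "me2",  "me3",  "prop",  "ph",    "Kacme"),
    targets = c("K",     "K",    "K",    "K",    "K,Nterm", "S,T,Y", "K"),
    formula = c("C2H2O", "CH2",  "C2H4", "C3H6", "C3H4O", "HPO3",  "C3H4O"),
    stringsAsFactors = FALSE
  )
  reg$delta <- vapply(reg$formula, formula_mass, numeric(1))
  reg
}

#' Load a modification registry from a config file
#'
#' Plain-text config, one modification per line:
#' \code{name<TAB or comma>targets<TAB or comma>formula}. Lines starting
#' with \code{#} are ignored. The monoisotopic delta is computed from the
#' formula.
#'
#' @param path file path.
#' @return registry data.frame as [default_modifications()].
#' @export
read_modifications <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[,\t]+")
  bad <- lengths(fields) != 3L
  if (any(bad)) stop("malformed modification config line(s): ",
                     paste(lines[bad], collapse = "; "))
  reg <- data.frame(
    name = vapply(fields, `[`, "", 1L),
    targets = vapply(fields, `[`, "", 2L),
    formula = vapply(fields, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(reg$name)) stop("duplicate modification names in config")
  reg$delta <- vapply(reg$formula, formula_mass, numeric(1))
  reg
}

#' Monoisotopic mass shift of a modification
#'
#' @param name modification short code (e.g. \code{"ac"}, \code{"me3"}).
#' @param registry modification registry (default [default_modifications()]).
#' @return mass shift in Da.
#' @examples
#' round(modification_delta("me3"), 3) # 42.047
#' round(modification_delta("ac"), 3)  # 42.011
#' @export
modification_delta <- function(name, registry = default_modifications()) {
  i <- match(name, registry$name)
  if (anyNA(i)) stop("unknown modification: ",
                     paste(name[is.na(i)], collapse = ", "))
  registry$delta[i]
}

# ---- Peptide forms -----------------------------------------------------------

#' Construct a modified peptide form
#'
#' A peptide form is one derivatized histone peptide with an exact PTM
#' placement: the unit of identification and quantification. Positions are
#' 1-based within the peptide; protein coordinates follow histone convention
#' (numbering after initiator-Met removal).
#'
#' @param sequence uppercase residue string.
#' @param placements named character vector mapping peptide position (or
#'   \code{"Nterm"}) to a modification name, e.g. \code{c("5" = "ac")}.
#' @param protein protein identifier.
#' @param start 1-based protein coordinate of the first residue.
#' @param registry modification registry.
#' @return object of class \code{peptide_form}.
#' @export
peptide_form <- function(sequence, placements = character(0),
                         protein = NA_character_, start = 1L,
                         registry = default_modifications()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% names(.RESIDUE_FORMULA)))
    stop("unknown residue code(s): ",
         paste(unique(res[!res %in% names(.RESIDUE_FORMULA)]), collapse = ","))
  placements <- .normalize_placements(placements)
  for (pos in names(placements)) {
    mod <- placements[[pos]]
    mi <- match(mod, registry$name)
    if (is.na(mi)) stop("unknown modification: ", mod)
    targets <- strsplit(registry$targets[mi], ",")[[1]]
    if (pos == "Nterm") {
      if (!"Nterm" %in% targets)
        stop("modification '", mod, "' does not target the N-terminus")
    } else {
      p <- as.integer(pos)
      if (is.na(p) || p < 1L || p > length(res))
        stop("placement position out of range: ", pos)
      if (!res[p] %in% targets)
        stop("residue ", res[p], p, " is not a valid target for '", mod, "'")
    }
  }
  structure(list(sequence = sequence, placements = placements,
                 protein = protein, start = as.integer(start),
                 end = as.integer(start) + nchar(sequence) - 1L),
            class = "peptide_form")
}

.normalize_placements <- function(placements) {
  if (length(placements) == 0L) return(stats::setNames(character(0), character(0)))
  placements <- unlist(placements)
  nm <- names(placements)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("placements must be a named vector (position or 'Nterm' -> mod)")
  # sort: Nterm first, then numeric position
  ord <- order(nm != "Nterm", suppressWarnings(as.integer(nm)), placements)
  placements[ord]
}

#' @export
print.peptide_form <- function(x, ...) {
  cat("<peptide_form> ", form_id(x), "\n", sep = "")
  invisible(x)
}

#' Compact identifier of a form
#'
#' Builds ids such as \code{"H4_4-17_K8ac"} (protein coordinates) or
#' \code{"GKGGKGLGKGGAKR_K5ac"} for anonymous peptides. Propionyl groups
#' added by derivatization are omitted from the id.
#'
#' @param form a \code{peptide_form}.
#' @param with_derivatization include prop placements in the id.
#' @return character id.
#' @export
form_id <- function(form, with_derivatization = FALSE) {
  res <- strsplit(form$sequence, "")[[1]]
  pl <- form$placements
  if (!with_derivatization) pl <- pl[pl != "prop"]
  lab <- character(0)
  for (pos in names(pl)) {
    if (pos == "Nterm") lab <- c(lab, paste0("Nt", pl[[pos]]))
    else {
      p <- as.integer(pos)
      prot_pos <- form$start + p - 1L
      lab <- c(lab, paste0(res[p], prot_pos, pl[[pos]]))
    }
  }
  base <- if (!is.na(form$protein))
    paste0(form$protein, "_", form$start, "-", form$end)
  else form$sequence
  if (length(lab)) paste0(base, "_", paste(lab, collapse = "")) else
    paste0(base, "_un")
}

#' Apply propionyl derivatization to a peptide form
#'
#' Chemical propionylation adds a propionyl group to the peptide N-terminus
#' and to every lysine epsilon-amine that is free or monomethylated;
#' acetylated, dimethylated and trimethylated lysines are blocked. This
#' mirrors complete derivatization of a histone digest.
#'
#' @param form a \code{peptide_form} with biological PTMs placed and no
#'   derivatization yet.
#' @return the derivatized \code{peptide_form}.
#' @export
apply_propionylation <- function(form) {
  if ("prop" %in% form$placements)
    stop("form is already derivatized")
  res <- strsplit(form$sequence, "")[[1]]
  pl <- as.list(form$placements)
  blocked <- c("ac", "me2", "me3", "Kacme")
  for (i in which(res == "K")) {
    key <- as.character(i)
    cur <- if (key %in% names(pl)) pl[[key]] else NA_character_
    if (is.na(cur)) {
      pl[[key]] <- "prop"
    } else if (cur == "me1") {
      # monomethyl-lysine retains a reactive proton: carries me1 + prop;
      # encode as the combined placement list entry
      pl[[paste0(key, "+")]] <- "prop"
    } # ac/me2/me3/Kacme blocked
  }
  if (!"Nterm" %in% names(pl)) pl[["Nterm"]] <- "prop"
  out <- form
  out$placements <- .normalize_placements(unlist(pl))
  out
}

# positions carrying 'me1 + prop' are encoded as "<pos>+" -> prop
.placement_positions <- function(placements) {
  nm <- names(placements)
  sub("\\+$", "", nm)
}

#' Neutral monoisotopic mass of a form
#'
#' Sum of residue masses, one water, and all placed modification deltas.
#'
#' @param form a \code{peptide_form} (or plain sequence string).
#' @param registry modification registry.
#' @return neutral mass in Da.
#' @export
monoisotopic_mass <- function(form, registry = default_modifications()) {
  if (is.character(form)) form <- peptide_form(form)
  res <- strsplit(form$sequence, "")[[1]]
  m <- sum(vapply(.RESIDUE_FORMULA[res], formula_mass, numeric(1))) +
    .WATER_MASS
  if (length(form$placements))
    m <- m + sum(modification_delta(unname(form$placements), registry))
  m
}

#' Elemental composition of a form
#'
#' @inheritParams monoisotopic_mass
#' @return named element count vector.
#' @export
form_composition <- function(form, registry = default_modifications()) {
  if (is.character(form)) form <- peptide_form(form)
  res <- strsplit(form$sequence, "")[[1]]
  comp <- c(H = 2L, O = 1L) # water
  for (r in res) comp <- .comp_add(comp, parse_formula(.RESIDUE_FORMULA[[r]]))
  for (mod in form$placements) {
    i <- match(mod, registry$name)
    comp <- .comp_add(comp, parse_formula(registry$formula[i]))
  }
  comp[comp != 0L]
}

#' Precursor m/z of a neutral mass at a charge
#'
#' @param mass neutral monoisotopic mass (Da).
#' @param charge positive integer charge.
#' @return m/z = (mass + charge * proton) / charge.
#' @export
precursor_mz <- function(mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (mass + charge * .PROTON_MASS) / charge
}

#' b/y fragment ion series of a form
#'
#' All b_i and y_i singly (or \code{product_charge}-) charged fragment m/z
#' values, with placed modifications (including derivatization) counted in
#' the covered span. N-terminal modifications belong to every b ion; the
#' full-length y ion carries them too.
#'
#' @param form a \code{peptide_form}.
#' @param ion_types subset of \code{c("b", "y")}.
#' @param product_charge product ion charge (DIA histone work uses 1).
#' @param registry modification registry.
#' @return data.frame with columns ion ("b"/"y"), index, label ("b3", "y10"),
#'   mz, and the neutral fragment mass.
#' @export
fragment_mz_series <- function(form, ion_types = c("b", "y"),
                               product_charge = 1L,
                               registry = default_modifications()) {
  if (is.character(form)) form <- peptide_form(form)
  res <- strsplit(form$sequence, "")[[1]]
  n <- length(res)
  res_mass <- vapply(.RESIDUE_FORMULA[res], formula_mass, numeric(1))
  # per-position modification mass (Nterm assigned to position 0)
  mod_mass <- numeric(n)
  nterm_mass <- 0
  for (k in seq_along(form$placements)) {
    pos <- .placement_positions(form$placements)[k]
    d <- modification_delta(form$placements[[k]], registry)
    if (pos == "Nterm") nterm_mass <- nterm_mass + d
    else mod_mass[as.integer(pos)] <- mod_mass[as.integer(pos)] + d
  }
  cum_n <- cumsum(res_mass + mod_mass) # N-terminal partial sums
  total <- cum_n[n] + nterm_mass + .WATER_MASS
  out <- list()
  if ("b" %in% ion_types) {
    i <- seq_len(n - 1L)
    neutral <- cum_n[i] + nterm_mass
    out$b <- data.frame(ion = "b", index = i, label = paste0("b", i),
                        neutral = neutral,
                        mz = (neutral + product_charge * .PROTON_MASS) /
                          product_charge)
  }
  if ("y" %in% ion_types) {
    i <- seq_len(n) # y_n = full length (equals precursor at same charge)
    prefix <- c(0, cum_n + nterm_mass) # mass removed from the N-terminal side
    neutral <- total - prefix[n - i + 1]
    out$y <- data.frame(ion = "y", index = i, label = paste0("y", i),
                        neutral = neutral,
                        mz = (neutral + product_charge * .PROTON_MASS) /
                          product_charge)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- Isotope envelopes -------------------------------------------------------

# Distribution of extra-neutron count for `count` atoms of one element,
# truncated to 0..(n-1) extra neutrons. Returns probability vector length n.
.element_isotope_dist <- function(element, count, n) {
  iso <- .ISOTOPES[[element]]
  # single-atom distribution over extra nucleons
  single <- numeric(n)
  extra <- round(iso[, "mass"] - iso[1, "mass"]) # 0,1,2,...
  for (j in seq_len(nrow(iso))) {
    k <- extra[j] + 1
    if (k <= n) single[k] <- single[k] + iso[j, "ab"]
  }
  # exponentiate by repeated truncated convolution (binary powering)
  resd <- c(1, numeric(n - 1))
  base <- single
  cnt <- count
  while (cnt > 0) {
    if (cnt %% 2 == 1) resd <- .conv_trunc(resd, base, n)
    base <- .conv_trunc(base, base, n)
    cnt <- cnt %/% 2
  }
  resd
}

.conv_trunc <- function(a, b, n) {
  out <- numeric(n)
  for (k in seq_len(n)) {
    i <- seq_len(k)
    out[k] <- sum(a[i] * b[k - i + 1])
  }
  out
}

#' Isotope envelope of a charged form
#'
#' First \code{n_peaks} isotopologue peaks computed by exact truncated
#' convolution of the elemental isotope distributions (compositions are
#' always known here, so no averagine approximation is needed). Intensities
#' are normalized to max = 1; peak spacing is 1.00336/charge m/z.
#'
#' @param form a \code{peptide_form}, composition vector, or formula string.
#' @param charge precursor charge.
#' @param n_peaks number of isotope peaks (DIA histone searches use 3).
#' @param registry modification registry.
#' @return object of class \code{isotope_envelope}: data.frame(mz, intensity).
#' @export
isotope_envelope <- function(form, charge = 1L, n_peaks = 3L,
                             registry = default_modifications()) {
  comp <- if (inherits(form, "peptide_form")) form_composition(form, registry)
          else if (is.character(form)) {
            if (grepl("^[A-Z][a-z0-9A-Z]*$", form) &&
                all(strsplit(form, "")[[1]] %in% names(.RESIDUE_FORMULA)) &&
                nchar(form) > 1)
              form_composition(peptide_form(form), registry)
            else parse_formula(form)
          } else form
  mono <- formula_mass(comp)
  dist <- c(1, numeric(n_peaks - 1))
  for (el in names(comp)) {
    if (comp[[el]] > 0)
      dist <- .conv_trunc(dist, .element_isotope_dist(el, comp[[el]], n_peaks),
                          n_peaks)
  }
  intensity <- dist / max(dist)
  mz <- (mono + (seq_len(n_peaks) - 1) * .NEUTRON_SPACING +
           charge * .PROTON_MASS) / charge
  structure(data.frame(mz = mz, intensity = intensity),
            class = c("isotope_envelope", "data.frame"))
}
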