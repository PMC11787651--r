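# Target database construction: derivatized tryptic digestion, PTM form
# enumeration, isobaric grouping, CSV export/import.

#' In-silico digestion of a propionylated protein
#'
#' Trypsin on a fully propionylated histone cleaves only after arginine
#' (lysine is blocked by the propionyl group), and not before proline
#' (the "[R|P]" rule), with zero missed cleavages.
#'
#' @param sequence uppercase residue string (post-initiator-Met numbering).
#' @param protein optional protein id recorded on each peptide.
#' @return data.frame with columns protein, start, end, sequence; spans are
#'   1-based inclusive and partition the input.
#' @export
digest <- function(sequence, protein = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% names(.RESIDUE_FORMULA)))
    stop("invalid residue code(s): ",
         paste(unique(res[!res %in% names(.RESIDUE_FORMULA)]), collapse = ","))
  n <- length(res)
  cut_after <- which(res == "R")
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  data.frame(protein = protein, start = starts, end = ends,
             sequence = vapply(seq_along(starts), function(i)
               substr(sequence, starts[i], ends[i]), ""),
             stringsAsFactors = FALSE)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper around \code{Biostrings::readAAStringSet}. Histone
#' community numbering drops the initiator methionine, so a leading M is
#' trimmed by default.
#'
#' @param path FASTA file.
#' @param trim_met drop a leading initiator Met (default TRUE).
#' @return named character vector of sequences (first word of header as name).
#' @export
read_proteins <- function(path, trim_met = TRUE) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  if (trim_met) seqs <- sub("^M", "", seqs)
  seqs
}

#' Enumerate modified forms of a digest peptide
#'
#' Places every combination of allowed residue modifications (one PTM per
#' site, up to \code{max_mods} simultaneous PTMs), then applies complete
#' propionyl derivatization to each. Output order is deterministic:
#' ascending number of PTMs, then lexicographic by (positions, mod names).
#'
#' @param peptide a sequence string or one row of [digest()] output.
#' @param allowed_mods named list mapping residue code to modification
#'   names, e.g. \code{list(K = "ac")} or \code{list(K = c("ac", "me3"))}.
#' @param max_mods maximum simultaneous PTMs per peptide.
#' @param protein,start protein id and 1-based start coordinate (overridden
#'   by \code{peptide} when it is a data.frame row).
#' @param registry modification registry.
#' @return list of derivatized \code{peptide_form} objects.
#' @export
enumerate_forms <- function(peptide, allowed_mods = list(),
                            max_mods = 2L,
                            protein = NA_character_, start = 1L,
                            registry = default_modifications()) {
  if (is.data.frame(peptide)) {
    stopifnot(nrow(peptide) == 1L)
    protein <- peptide$protein; start <- peptide$start
    peptide <- peptide$sequence
  }
  res <- strsplit(peptide, "")[[1]]
  # site options: list of (pos, mod) candidates
  sites <- list()
  for (i in seq_along(res)) {
    mods <- allowed_mods[[res[i]]]
    if (length(mods))
      sites[[length(sites) + 1L]] <- list(pos = i, mods = sort(mods))
  }
  placements_sets <- list(character(0)) # unmodified
  if (length(sites) && max_mods >= 1L) {
    for (k in seq_len(min(max_mods, length(sites)))) {
      combos <- utils::combn(length(sites), k, simplify = FALSE)
      for (cmb in combos) {
        mod_choices <- lapply(sites[cmb], `[[`, "mods")
        grid <- do.call(expand.grid,
                        c(rev(mod_choices), stringsAsFactors = FALSE))
        grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
        for (r in seq_len(nrow(grid))) {
          pl <- stats::setNames(as.character(unlist(grid[r, ])),
                                as.character(vapply(sites[cmb], `[[`, 0L,
                                                    "pos")))
          placements_sets[[length(placements_sets) + 1L]] <- pl
        }
      }
    }
  }
  # deterministic order: number of mods, then positions, then mod names
  key <- vapply(placements_sets, function(pl)
    paste(length(pl),
          paste(formatC(as.integer(names(pl)), width = 4, flag = "0"),
                pl, collapse = "|"), sep = "#"), "")
  placements_sets <- placements_sets[order(key)]
  lapply(placements_sets, function(pl) {
    f <- peptide_form(peptide, placements = pl, protein = protein,
                      start = start, registry = registry)
    apply_propionylation(f)
  })
}

#' Group forms that are isobaric at a charge state
#'
#' Partitions forms of a shared backbone by precursor m/z proximity:
#' positional isomers (identical composition) always co-group, and forms
#' closer than \code{ppm_tol} chain into one group. Grouping is performed
#' on sorted m/z, so it is independent of input order.
#'
#' @param forms list of \code{peptide_form}s sharing a backbone sequence.
#' @param charge precursor charge for the grouping.
#' @param ppm_tol grouping tolerance in ppm (default: the 10 ppm MS1
#'   tolerance).
#' @param registry modification registry.
#' @return list of \code{isomer_group} objects: list(members, mz, charge,
#'   sites) where sites are the ordered candidate modification positions.
#' @export
group_isobaric <- function(forms, charge = 2L, ppm_tol = 10,
                           registry = default_modifications()) {
  stopifnot(length(forms) >= 1L)
  seqs <- vapply(forms, `[[`, "", "sequence")
  if (length(unique(seqs)) != 1L)
    stop("forms must share one backbone sequence")
  mz <- vapply(forms, function(f)
    precursor_mz(monoisotopic_mass(f, registry), charge), numeric(1))
  ord <- order(mz, vapply(forms, form_id, ""))
  mz_s <- mz[ord]
  gap_ppm <- diff(mz_s) / mz_s[-length(mz_s)] * 1e6
  grp <- cumsum(c(1, as.integer(gap_ppm > ppm_tol)))
  lapply(split(ord, grp), function(idx) {
    members <- forms[idx]
    sites <- sort(unique(unlist(lapply(members, function(f) {
      pos <- .placement_positions(f$placements)
      as.integer(pos[pos != "Nterm" & f$placements != "prop"])
    }))))
    structure(list(members = members,
                   mz = mean(mz[idx]),
                   charge = charge,
                   sites = sites),
              class = "isomer_group")
  })
}

#' @export
print.isomer_group <- function(x, ...) {
  cat("<isomer_group> ", length(x$members), " form(s) at m/z ",
      sprintf("%.4f", x$mz), " (", x$charge, "+)\n", sep = "")
  for (m in x$members) cat("  ", form_id(m), "\n", sep = "")
  invisible(x)
}

# ---- Target database ---------------------------------------------------------

.serialize_placements <- function(placements) {
  if (!length(placements)) return("")
  paste(names(placements), unname(placements), sep = ":", collapse = ";")
}

.deserialize_placements <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  parts <- strsplit(strsplit(s, ";")[[1]], ":")
  stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
}

#' Build a searchable target database
#'
#' Digests each protein under derivatized-trypsin rules, enumerates PTM
#' forms per peptide, and tabulates neutral mass and per-charge precursor
#' m/z. Peptides whose precursor falls outside \code{mz_range} at every
#' charge are dropped.
#'
#' @param proteins named character vector of protein sequences
#'   (post-Met numbering, as from [read_proteins()]).
#' @param allowed_mods named list residue -> modification names.
#' @param max_mods max simultaneous PTMs per peptide.
#' @param charges precursor charge states (histone DIA uses 2:4).
#' @param mz_range keep forms with at least one charge state inside this
#'   precursor window.
#' @param min_length minimum peptide length to retain.
#' @param registry modification registry.
#' @return data.frame (class \code{target_db}) with one row per
#'   (form, charge): form_id, protein, start, end, sequence, placements
#'   (serialized), neutral_mass, charge, mz.
#' @export
build_target_db <- function(proteins, allowed_mods = list(K = c("ac")),
                            max_mods = 2L, charges = 2:4,
                            mz_range = c(300, 900), min_length = 4L,
                            registry = default_modifications()) {
  rows <- list()
  for (prot in names(proteins)) {
    peps <- digest(proteins[[prot]], protein = prot)
    peps <- peps[nchar(peps$sequence) >= min_length, , drop = FALSE]
    for (i in seq_len(nrow(peps))) {
      forms <- enumerate_forms(peps[i, ], allowed_mods, max_mods,
                               registry = registry)
      for (f in forms) {
        mass <- monoisotopic_mass(f, registry)
        for (z in charges) {
          mz <- precursor_mz(mass, z)
          if (mz >= mz_range[1] && mz <= mz_range[2]) {
            rows[[length(rows) + 1L]] <- data.frame(
              form_id = form_id(f), protein = prot,
              start = f$start, end = f$end, sequence = f$sequence,
              placements = .serialize_placements(f$placements),
              neutral_mass = mass, charge = z, mz = mz,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  db <- if (length(rows)) do.call(rbind, rows) else
    data.frame(form_id = character(0), protein = character(0),
               start = integer(0), end = integer(0), sequence = character(0),
               placements = character(0), neutral_mass = numeric(0),
               charge = integer(0), mz = numeric(0))
  class(db) <- c("target_db", "data.frame")
  db
}

#' Reconstruct a \code{peptide_form} from a target-db row
#' @param row one-row data.frame with sequence, placements, protein, start.
#' @return a \code{peptide_form}.
#' @export
db_row_form <- function(row) {
  f <- peptide_form(row$sequence,
                    protein = row$protein, start = row$start)
  f$placements <- .normalize_placements(.deserialize_placements(row$placements))
  f
}

#' Write / read a target database as CSV
#' @param db a \code{target_db} data.frame.
#' @param path CSV path.
#' @export
write_target_db <- function(db, path) {
  utils::write.csv(as.data.frame(db), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_target_db
#' @export
read_target_db <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(placements = "character"))
  db$placements[is.na(db$placements)] <- ""
  class(db) <- c("target_db", "data.frame")
  db
}
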