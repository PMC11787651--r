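# DIA run model and I/O: mzML/mzXML reading via mzR, mzML writing (for the
# simulator), and the plain-text ms1/ms2 spectral dialect consumed by
# targeted histone search tools.

#' Construct a DIA run from spectra
#'
#' A run is an ordered list of spectra; each spectrum is a list with scan,
#' ms_level, rt (minutes), mz, intensity and, for MS2, window_low,
#' window_high, precursor_mz. Cycle structure (one MS1 followed by the
#' scheme's MS2 windows) is derived: a new cycle starts at each MS1 scan.
#'
#' @param spectra list of spectrum lists.
#' @param cycle_time_s optional acquisition cycle time (s), metadata.
#' @return object of class \code{dia_run}.
#' @export
dia_run <- function(spectra, cycle_time_s = NA_real_) {
  rt <- vapply(spectra, `[[`, numeric(1), "rt")
  if (length(rt) > 1 && any(diff(rt) < -1e-9))
    stop("retention times must be nondecreasing across the run")
  lev <- vapply(spectra, `[[`, numeric(1), "ms_level")
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (length(sp$mz) != length(sp$intensity))
      stop("spectrum ", i, ": m/z and intensity lengths differ")
    if (lev[i] == 2 &&
        (is.null(sp$window_low) || is.na(sp$window_low) ||
         is.null(sp$window_high) || is.na(sp$window_high)))
      stop("MS2 scan ", i, " has no isolation window")
  }
  cycle <- cumsum(lev == 1)
  structure(list(spectra = spectra, cycle = cycle,
                 cycle_time_s = cycle_time_s),
            class = "dia_run")
}

#' @export
print.dia_run <- function(x, ...) {
  lev <- vapply(x$spectra, `[[`, numeric(1), "ms_level")
  cat("<dia_run> ", length(x$spectra), " spectra (",
      sum(lev == 1), " MS1 / ", sum(lev == 2), " MS2), ",
      max(c(x$cycle, 0)), " cycles\n", sep = "")
  invisible(x)
}

#' Number of cycles in a run
#' @param run a \code{dia_run}.
#' @export
n_cycles <- function(run) max(c(run$cycle, 0L))

#' Distinct isolation windows of a run, in cycle order
#' @param run a \code{dia_run}.
#' @return data.frame(low, high) keyed at 2 dp.
#' @export
run_windows <- function(run) {
  meta <- attr(run, "spec_meta")
  lev <- if (!is.null(meta)) meta$lev else
    vapply(run$spectra, `[[`, numeric(1), "ms_level")
  ms2 <- run$spectra[lev == 2]
  if (!length(ms2)) return(data.frame(low = numeric(0), high = numeric(0)))
  key <- vapply(ms2, function(s)
    sprintf("%.2f|%.2f", s$window_low, s$window_high), "")
  u <- !duplicated(key)
  data.frame(low = vapply(ms2[u], `[[`, numeric(1), "window_low"),
             high = vapply(ms2[u], `[[`, numeric(1), "window_high"))
}

#' Read a DIA run from mzML or mzXML
#'
#' Parses centroided spectra with retention time, MS level and (for MS2)
#' the isolation window, and infers the cycle structure from the repeating
#' window sequence. Profile-mode data and MS2 scans without an isolation
#' window are rejected.
#'
#' @param path mzML or mzXML file.
#' @return a \code{dia_run}.
#' @export
read_dia_run <- function(path) {
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (nrow(h) == 1L) pk <- list(pk)
  if (any(!is.na(h$centroided) & !h$centroided))
    stop("profile-mode spectra are not supported; centroid upstream")
  spectra <- vector("list", nrow(h))
  for (i in seq_len(nrow(h))) {
    p <- pk[[i]]
    sp <- list(scan = h$acquisitionNum[i],
               ms_level = h$msLevel[i],
               rt = h$retentionTime[i] / 60, # mzR reports seconds
               mz = as.numeric(p[, 1]),
               intensity = as.numeric(p[, 2]))
    if (h$msLevel[i] == 2) {
      tgt <- h$isolationWindowTargetMZ[i]
      lo <- h$isolationWindowLowerOffset[i]
      hi <- h$isolationWindowUpperOffset[i]
      if (is.na(tgt) || is.na(lo) || is.na(hi))
        stop("MS2 scan ", h$acquisitionNum[i], " has no isolation window")
      sp$window_low <- tgt - lo
      sp$window_high <- tgt + hi
      sp$precursor_mz <- if (!is.na(h$precursorMZ[i])) h$precursorMZ[i] else tgt
    }
    spectra[[i]] <- sp
  }
  rts <- h$retentionTime[h$msLevel == 1] / 60
  ct <- if (length(rts) > 1) stats::median(diff(rts)) * 60 else NA_real_
  dia_run(spectra, cycle_time_s = ct)
}

#' Write a DIA run to mzML
#'
#' @param run a \code{dia_run}.
#' @param path output mzML path.
#' @export
write_dia_run <- function(run, path) {
  n <- length(run$spectra)
  lev <- vapply(run$spectra, `[[`, numeric(1), "ms_level")
  rt_s <- vapply(run$spectra, `[[`, numeric(1), "rt") * 60
  get_or <- function(s, f, d) if (!is.null(s[[f]])) s[[f]] else d
  wl <- vapply(run$spectra, get_or, numeric(1), "window_low", NA_real_)
  wh <- vapply(run$spectra, get_or, numeric(1), "window_high", NA_real_)
  pmz <- vapply(run$spectra, get_or, numeric(1), "precursor_mz", NA_real_)
  pmz[lev == 2 & is.na(pmz)] <- ((wl + wh) / 2)[lev == 2 & is.na(pmz)]
  npk <- vapply(run$spectra, function(s) length(s$mz), integer(1))
  tic <- vapply(run$spectra, function(s) sum(s$intensity), numeric(1))
  bpi <- vapply(run$spectra, function(s)
    if (length(s$intensity)) max(s$intensity) else 0, numeric(1))
  bpm <- vapply(run$spectra, function(s)
    if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1))
  lomz <- vapply(run$spectra, function(s)
    if (length(s$mz)) min(s$mz) else 0, numeric(1))
  himz <- vapply(run$spectra, function(s)
    if (length(s$mz)) max(s$mz) else 0, numeric(1))
  h <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(lev), polarity = 1L,
    peaksCount = npk, totIonCurrent = tic, retentionTime = rt_s,
    basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = ifelse(lev == 2, 30, 0), ionisationEnergy = 0,
    lowMZ = lomz, highMZ = himz,
    precursorScanNum = 0L, precursorMZ = pmz,
    precursorCharge = NA_integer_, precursorIntensity = NA_real_,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = (wl + wh) / 2,
    isolationWindowLowerOffset = (wh - wl) / 2,
    isolationWindowUpperOffset = (wh - wl) / 2,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  pk <- lapply(run$spectra, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pk, path, header = h, outformat = "mzml")
  invisible(path)
}

# ---- ms1/ms2 text dialect ----------------------------------------------------

# S/I/Z record dialect: "H" header lines; per scan "S <scan> <scan>" (ms2
# adds the nominal precursor m/z), "I RTime <minutes>" (4 dp), ms2
# "I IsoWindow <low> <high>" plus "Z <charge> <M+H>" lines, then
# "m/z intensity" pairs (m/z 5 dp).

#' Convert a DIA run to ms1 and ms2 text files
#'
#' Splits a run into the plain-text ms1 (MS1 scans) and ms2 (MS2 scans)
#' spectral formats. When the precursor charge is unknown the ms2 file
#' carries Z lines for charges 2-4, matching the histone search space.
#'
#' @param run a \code{dia_run}.
#' @param out_prefix output path prefix; writes \code{<prefix>.ms1} and
#'   \code{<prefix>.ms2}.
#' @param charges Z-line charges emitted when the precursor charge is
#'   unknown.
#' @return character(2): the two paths written.
#' @export
write_ms1_ms2 <- function(run, out_prefix, charges = 2:4) {
  lev <- vapply(run$spectra, `[[`, numeric(1), "ms_level")
  hdr <- c(
    paste0("H\tCreationDate\t", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "H\tExtractor\thistoneDIA",
    "H\tComments\tconverted DIA run")
  fmt_scan <- function(s, is_ms2) {
    out <- character(0)
    if (is_ms2) {
      pmz <- round(s$precursor_mz, 5) # printed precision drives Z lines
      out <- c(out, sprintf("S\t%06d\t%06d\t%.5f", s$scan, s$scan, pmz))
      out <- c(out, sprintf("I\tRTime\t%.4f", s$rt))
      out <- c(out, sprintf("I\tIsoWindow\t%.4f\t%.4f",
                            s$window_low, s$window_high))
      for (z in charges)
        out <- c(out, sprintf("Z\t%d\t%.5f",
                              z, pmz * z - (z - 1) * .PROTON_MASS))
    } else {
      out <- c(out, sprintf("S\t%06d\t%06d", s$scan, s$scan))
      out <- c(out, sprintf("I\tRTime\t%.4f", s$rt))
    }
    if (length(s$mz))
      out <- c(out, sprintf("%.5f %s", s$mz, format(s$intensity,
                                                    trim = TRUE,
                                                    scientific = FALSE)))
    out
  }
  ms1_path <- paste0(out_prefix, ".ms1")
  ms2_path <- paste0(out_prefix, ".ms2")
  ms1_lines <- unlist(lapply(run$spectra[lev == 1], fmt_scan, is_ms2 = FALSE))
  ms2_lines <- unlist(lapply(run$spectra[lev == 2], fmt_scan, is_ms2 = TRUE))
  writeLines(c(hdr, ms1_lines), ms1_path)
  writeLines(c(hdr, ms2_lines), ms2_path)
  invisible(c(ms1_path, ms2_path))
}

# Parse one ms1/ms2 file into a list of spectrum lists.
.read_msn <- function(path, ms_level) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "H")]
  spectra <- list()
  cur <- NULL
  flush <- function(cur, spectra) {
    if (!is.null(cur)) spectra[[length(spectra) + 1L]] <- cur
    spectra
  }
  for (ln in lines) {
    if (startsWith(ln, "S")) {
      spectra <- flush(cur, spectra)
      f <- strsplit(ln, "\t")[[1]]
      cur <- list(scan = as.integer(f[2]), ms_level = ms_level,
                  rt = NA_real_, mz = numeric(0), intensity = numeric(0))
      if (ms_level == 2 && length(f) >= 4)
        cur$precursor_mz <- as.numeric(f[4])
    } else if (startsWith(ln, "I")) {
      f <- strsplit(ln, "\t")[[1]]
      if (f[2] == "RTime") cur$rt <- as.numeric(f[3])
      if (f[2] == "IsoWindow") {
        cur$window_low <- as.numeric(f[3])
        cur$window_high <- as.numeric(f[4])
      }
    } else if (startsWith(ln, "Z")) {
      # charge lines carry no information we do not already model
    } else if (nzchar(trimws(ln))) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      cur$mz <- c(cur$mz, as.numeric(f[1]))
      cur$intensity <- c(cur$intensity, as.numeric(f[2]))
    }
  }
  flush(cur, spectra)
}

#' Read ms1/ms2 text files back into a DIA run
#'
#' Reassembles a \code{dia_run} from a pair of ms1/ms2 files written by
#' [write_ms1_ms2()], interleaving scans by scan number.
#'
#' @param prefix path prefix used when writing (\code{<prefix>.ms1/.ms2}),
#'   or the ms1 path (its sibling ms2 is found by extension).
#' @return a \code{dia_run}.
#' @export
read_ms1_ms2 <- function(prefix) {
  if (grepl("\\.ms1$", prefix)) prefix <- sub("\\.ms1$", "", prefix)
  ms1 <- .read_msn(paste0(prefix, ".ms1"), 1L)
  ms2 <- if (file.exists(paste0(prefix, ".ms2")))
    .read_msn(paste0(prefix, ".ms2"), 2L) else list()
  spectra <- c(ms1, ms2)
  ord <- order(vapply(spectra, `[[`, numeric(1), "scan"))
  dia_run(spectra[ord])
}
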