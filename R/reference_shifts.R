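# Literature-derived reference chemical-shift statistics used by the
# classifiers.  The secondary-structure means/SDs (Wang & Jardetzky 2002)
# and proline isomer shifts are transcriptions from the cited literature
# shipped as versioned TSVs under inst/extdata; the glutamate protonation
# cross-peak references are the standard values for the ionisable side
# chain.  All shifts are on the DSS scale; the loader refuses tables that
# declare a different reference compound.

#' Load the packaged (or user-supplied) reference chemical-shift tables
#'
#' Reads and validates the four reference tables used by the classifiers:
#' per-(residue, atom, class) secondary-structure means and SDs, the Glu
#' protonation-state Cgamma/Cdelta references, the proline cis/trans
#' Cbeta/Cgamma references with the delta(Cbeta)-delta(Cgamma)
#' discriminator threshold, and additive random-coil neighbour corrections.
#'
#' Validation enforces: sd > 0 for every secondary-structure entry; all
#' three classes (helix, sheet, coil) present for every (residue, atom)
#' pair; deprotonated Glu Cdelta more deshielded than protonated; the cis
#' proline Cbeta-Cgamma separation larger than trans with the threshold
#' strictly between them; finite corrections with context "none" mapping
#' to 0; and a DSS reference scale in the provenance sidecar.
#'
#' @param dir Directory holding the TSV tables and `reference_provenance.json`;
#'   defaults to the packaged data.
#' @return A list of class `reference_tables` with elements `shifts`
#'   (data frame), `protonation`, `proline`, `corrections`, `provenance`.
#' @examples
#' ref <- load_reference_tables()
#' subset(ref$shifts, residue == "A" & atom == "CA")
#' @export
load_reference_tables <- function(dir = system.file("extdata", package = "silknmr")) {
  read_tsv <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing reference table: ", path)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  shifts <- read_tsv("reference_shifts.tsv")
  prot <- read_tsv("glu_protonation.tsv")
  pro <- read_tsv("proline_isomer.tsv")
  corr <- read_tsv("random_coil_corrections.tsv")
  prov_path <- file.path(dir, "reference_provenance.json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path) else list()

  scale <- prov$reference_scale
  if (!is.null(scale) && !identical(scale, "DSS"))
    stop("reference tables declare scale '", scale, "'; only DSS is accepted")

  # secondary-structure table invariants
  need <- c("residue", "atom", "class", "mean_ppm", "sd_ppm")
  if (!all(need %in% names(shifts)))
    stop("reference_shifts.tsv must have columns ", paste(need, collapse = ", "))
  bad_sd <- shifts$sd_ppm <= 0
  if (any(bad_sd))
    stop("non-positive sd for key(s): ",
         paste(sprintf("%s/%s/%s", shifts$residue[bad_sd], shifts$atom[bad_sd],
                       shifts$class[bad_sd]), collapse = ", "))
  key <- paste(shifts$residue, shifts$atom)
  for (k in unique(key)) {
    cls <- shifts$class[key == k]
    missing <- setdiff(c("helix", "sheet", "coil"), cls)
    if (length(missing))
      stop("reference table missing class entries for ", k, ": ",
           paste(missing, collapse = ", "))
  }

  dep_cd <- prot$shift_ppm[prot$state == "deprotonated" & prot$atom == "CD"]
  pro_cd <- prot$shift_ppm[prot$state == "protonated" & prot$atom == "CD"]
  if (length(dep_cd) != 1L || length(pro_cd) != 1L || dep_cd <= pro_cd)
    stop("protonation reference invalid: deprotonated Cdelta must exceed protonated")

  dbg <- function(iso)
    pro$shift_ppm[pro$isomer == iso & pro$atom == "CB"] -
      pro$shift_ppm[pro$isomer == iso & pro$atom == "CG"]
  thr <- prov$tables$proline_isomer$delta_bg_threshold_ppm
  if (is.null(thr)) thr <- 7.0
  thr <- as.numeric(thr)
  if (!(dbg("cis") > dbg("trans")) || !(thr > dbg("trans") && thr < dbg("cis")))
    stop("proline isomer reference invalid: need Dbg(cis) > threshold > Dbg(trans)")

  if (any(!is.finite(corr$correction_ppm)))
    stop("non-finite random-coil correction")
  none0 <- corr$correction_ppm[corr$context == "none"]
  if (length(none0) && any(none0 != 0))
    stop("random-coil correction for context 'none' must be 0")

  structure(list(
    shifts = shifts,
    protonation = prot,
    proline = list(table = pro, delta_bg_threshold_ppm = thr,
                   delta_bg = c(trans = dbg("trans"), cis = dbg("cis"))),
    corrections = corr,
    provenance = prov
  ), class = "reference_tables")
}

#' @export
print.reference_tables <- function(x, ...) {
  cat(sprintf("reference_tables: %d secondary-structure entries (%s scale)\n",
              nrow(x$shifts),
              if (is.null(x$provenance$reference_scale)) "unknown"
              else x$provenance$reference_scale))
  invisible(x)
}

#' Random-coil mean shift with neighbour context correction
#'
#' @param tables A `reference_tables` object.
#' @param residue One-letter residue code.
#' @param atom Atom name (`"CA"`, `"CB"`).
#' @param context Neighbour context key, e.g. `"prePro"` for a preceding
#'   proline; `"none"` applies no correction.
#' @return Corrected random-coil mean in ppm.
#' @export
random_coil_shift <- function(tables, residue, atom, context = "none") {
  stopifnot(inherits(tables, "reference_tables"))
  row <- tables$shifts[tables$shifts$residue == residue &
                       tables$shifts$atom == atom &
                       tables$shifts$class == "coil", , drop = FALSE]
  if (nrow(row) == 0L)
    stop("no random-coil entry for ", residue, "/", atom)
  corr <- tables$corrections
  hit <- corr[corr$residue == residue & corr$atom == atom &
              corr$context == context, , drop = FALSE]
  delta <- if (nrow(hit)) hit$correction_ppm[1] else 0
  row$mean_ppm[1] + delta
}
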