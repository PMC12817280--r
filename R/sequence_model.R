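# Repeat-construct sequence model for engineered ADF4 silk variants:
# deterministic assembly of eADF4(Cn) sequences, motif scanning with
# repeat-junction bookkeeping, residue composition, and omega (peptide-bond)
# dihedral census of structural models.

.C_MODULE_REPEAT <- "GSSAAAAAAAASGPGGYGPENQGPSGPGGYGPGGP"
.TAGS <- list(T7 = "ASMTGGQQMGRGSM", none = "SM")
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build an eADF4(Cn) repeat construct
#'
#' Assembles the full amino-acid sequence of an engineered ADF4 variant:
#' an N-terminal tag, `n_repeats` exact copies of the 35-residue consensus
#' repeat (the "C module"), and a single trailing glycine.  The T7-tagged
#' variant corresponds to the column-free purified protein whose initiator
#' methionine is post-translationally cleaved; set `retain_met1 = TRUE` to
#' keep it.  The tag-free variant (as obtained after His-SUMO cleavage)
#' starts with "SM".
#'
#' @param n_repeats Number of C-module copies (>= 1); 16 gives eADF4(C16).
#' @param tag_variant `"T7"` or `"none"`.
#' @param retain_met1 Keep the initiator Met of the T7-tagged construct
#'   (default `FALSE`, matching the mature protein).
#' @return An object of class `repeat_construct` with components
#'   `n_repeats`, `tag_variant`, `tag`, `repeat_motif`, `full_sequence`, and
#'   `residue_index_map` (a data frame mapping every global 1-based position
#'   to its repeat number and within-repeat position; tag residues carry
#'   repeat number 0, the trailing Gly is position 1 of repeat
#'   `n_repeats + 1`).
#' @examples
#' c16 <- build_construct(16, "T7")
#' nchar(c16$full_sequence)  # 575
#' @export
build_construct <- function(n_repeats, tag_variant = c("T7", "none"),
                            retain_met1 = FALSE) {
  if (!is.numeric(n_repeats) || length(n_repeats) != 1L ||
      n_repeats < 1 || n_repeats != round(n_repeats))
    stop("'n_repeats' must be a positive integer")
  tag_variant <- match.arg(tag_variant)
  n_repeats <- as.integer(n_repeats)
  tag <- .TAGS[[tag_variant]]
  if (retain_met1 && tag_variant == "T7") tag <- paste0("M", tag)
  motif <- .C_MODULE_REPEAT
  full <- paste0(tag, strrep(motif, n_repeats), "G")

  ntag <- nchar(tag); nm <- nchar(motif)
  pos <- seq_len(nchar(full))
  repeat_number <- integer(length(pos))
  within <- integer(length(pos))
  repeat_number[pos <= ntag] <- 0L
  within[pos <= ntag] <- pos[pos <= ntag]
  body <- pos > ntag & pos <= ntag + n_repeats * nm
  off <- pos[body] - ntag - 1L
  repeat_number[body] <- off %/% nm + 1L
  within[body] <- off %% nm + 1L
  tail_g <- pos == nchar(full)
  repeat_number[tail_g] <- n_repeats + 1L
  within[tail_g] <- 1L

  structure(list(
    n_repeats = n_repeats,
    tag_variant = tag_variant,
    tag = tag,
    repeat_motif = motif,
    full_sequence = full,
    residue_index_map = data.frame(
      position = pos,
      residue = strsplit(full, "")[[1]],
      repeat_number = repeat_number,
      within_repeat = within
    )
  ), class = "repeat_construct")
}

#' @export
print.repeat_construct <- function(x, ...) {
  cat(sprintf("eADF4(C%d) construct [%s tag], %d residues\n",
              x$n_repeats, x$tag_variant, nchar(x$full_sequence)))
  invisible(x)
}

#' Find all (overlapping) occurrences of a sequence motif
#'
#' Scans the full construct sequence for every occurrence of `motif`,
#' including overlapping ones.  Because consecutive repeat copies abut
#' directly (each C module ends in Pro and starts with Gly), motifs that
#' span a repeat junction — such as the Pro35–Gly1 "PG" pair — are ordinary
#' substrings of the full sequence; `wrap_repeats` controls whether such
#' junction-spanning hits are reported (they are flagged
#' `crosses_junction`).  The default `TRUE` matches the convention of
#' counting the glycine that follows the previous repeat's terminal proline
#' as a PG-motif glycine (Gly1).
#'
#' @param construct A `repeat_construct`.
#' @param motif Non-empty uppercase one-letter amino-acid string.
#' @param wrap_repeats Include hits spanning repeat junctions (default TRUE).
#' @return Data frame with columns `motif`, `start` (1-based global),
#'   `repeat_number` (of the start position), `within_repeat` (of the start
#'   position), `crosses_junction`.
#' @examples
#' c16 <- build_construct(16, "T7")
#' pg <- find_motifs(c16, "PG")
#' nrow(pg)  # 64: four per repeat
#' @export
find_motifs <- function(construct, motif, wrap_repeats = TRUE) {
  stopifnot(inherits(construct, "repeat_construct"))
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L)
    stop("'motif' must be a non-empty string")
  letters_in <- strsplit(motif, "")[[1]]
  if (!all(letters_in %in% .AA20))
    stop("'motif' contains characters outside the 20-letter amino-acid alphabet: ",
         paste(unique(setdiff(letters_in, .AA20)), collapse = ", "))
  full <- construct$full_sequence
  m <- nchar(motif)
  starts <- integer(0)
  # overlapping scan
  hit <- gregexpr(paste0("(?=", motif, ")"), full, perl = TRUE)[[1]]
  if (hit[1] != -1) starts <- as.integer(hit)
  if (length(starts) == 0L)
    return(data.frame(motif = character(0), start = integer(0),
                      repeat_number = integer(0), within_repeat = integer(0),
                      crosses_junction = logical(0)))
  map <- construct$residue_index_map
  rep_start <- map$repeat_number[starts]
  rep_end <- map$repeat_number[starts + m - 1L]
  crosses <- rep_start != rep_end
  out <- data.frame(
    motif = motif,
    start = starts,
    repeat_number = rep_start,
    within_repeat = map$within_repeat[starts],
    crosses_junction = crosses
  )
  if (!wrap_repeats) out <- out[!out$crosses_junction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residue composition of a construct
#'
#' @param construct A `repeat_construct`.
#' @return Named integer vector of residue counts; the counts sum to the
#'   sequence length.
#' @examples
#' composition(build_construct(16, "T7"))[["E"]]  # 16
#' @export
composition <- function(construct) {
  stopifnot(inherits(construct, "repeat_construct"))
  tab <- table(factor(strsplit(construct$full_sequence, "")[[1]], levels = .AA20))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[counts > 0]
}

#' Positions of tag methionines
#'
#' The diagonal Met intensity in carbon spectra of tagged constructs stems
#' from the purification tag; this helper flags those positions without
#' making any quantitative claim about their signal contribution.
#'
#' @param construct A `repeat_construct`.
#' @return Integer vector of global positions of Met residues within the tag.
#' @export
tag_met_positions <- function(construct) {
  stopifnot(inherits(construct, "repeat_construct"))
  map <- construct$residue_index_map
  map$position[map$repeat_number == 0L & map$residue == "M"]
}

#' Write / read a construct as FASTA
#'
#' Round trip through FASTA preserves the sequence byte-exactly.
#'
#' @param construct A `repeat_construct`.
#' @param path Output FASTA path.
#' @param name Record name.
#' @return `write_construct_fasta`: the path, invisibly.
#' @export
write_construct_fasta <- function(construct, path, name = NULL) {
  stopifnot(inherits(construct, "repeat_construct"))
  if (is.null(name))
    name <- sprintf("eADF4_C%d_%s", construct$n_repeats, construct$tag_variant)
  aa <- Biostrings::AAStringSet(construct$full_sequence)
  names(aa) <- name
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' @rdname write_construct_fasta
#' @return `read_fasta_sequence`: named character vector of sequences.
#' @export
read_fasta_sequence <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- names(aa)
  out
}

# ---- omega (peptide-bond) dihedral census -------------------------------

#' Dihedral angle of four points, in degrees in (-180, 180]
#'
#' Standard signed torsion about the b2 axis (atan2 formulation), used for
#' the backbone omega angle CA(i-1)-C(i-1)-N(i)-CA(i).
#'
#' @param p1,p2,p3,p4 Numeric xyz coordinates.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Census of peptide-bond omega angles in a structural model
#'
#' Reads a PDB or mmCIF file, computes the omega dihedral
#' CA(i-1)–C(i-1)–N(i)–CA(i) for every consecutive residue pair within each
#' chain, and classifies the bond preceding residue i as cis
#' (|omega| < 90 deg) or trans (|omega| >= 90 deg; exact 90 is labelled
#' trans by convention).  Pairs with missing backbone atoms are skipped
#' with a warning.
#'
#' @param path Path to a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param residue_filter Optional three-letter residue name (e.g. `"PRO"`);
#'   only bonds whose *following* residue matches are reported.
#' @return Data frame with columns `chain`, `resno`, `resid` (the residue
#'   following the bond), `omega_deg`, `isomer`.
#' @export
omega_census <- function(path, residue_filter = NULL) {
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("could not parse structure file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$elety %in% c("CA", "C", "N") & !is.na(at$resno), , drop = FALSE]
  recs <- list()
  for (ch in unique(at$chain)) {
    cat_ch <- at[at$chain %in% ch, , drop = FALSE]
    resnos <- sort(unique(cat_ch$resno))
    if (length(resnos) < 2L) next
    get_atom <- function(resno, name) {
      row <- cat_ch[cat_ch$resno == resno & cat_ch$elety == name, , drop = FALSE]
      if (nrow(row) == 0L) return(NULL)
      as.numeric(row[1, c("x", "y", "z")])
    }
    for (k in 2:length(resnos)) {
      i_prev <- resnos[k - 1L]; i <- resnos[k]
      if (i != i_prev + 1L) next  # chain break
      ca0 <- get_atom(i_prev, "CA"); c0 <- get_atom(i_prev, "C")
      n1 <- get_atom(i, "N"); ca1 <- get_atom(i, "CA")
      if (is.null(ca0) || is.null(c0) || is.null(n1) || is.null(ca1)) {
        warning(sprintf("missing backbone atoms for bond %s%d-%d; skipped",
                        ch, i_prev, i))
        next
      }
      resid <- cat_ch$resid[cat_ch$resno == i][1]
      omega <- dihedral_angle(ca0, c0, n1, ca1)
      recs[[length(recs) + 1L]] <- data.frame(
        chain = ch, resno = i, resid = resid, omega_deg = omega,
        isomer = if (abs(omega) < 90) "cis" else "trans"
      )
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chain = character(0), resno = integer(0), resid = character(0),
               omega_deg = numeric(0), isomer = character(0))
  if (!is.null(residue_filter))
    out <- out[out$resid == residue_filter, , drop = FALSE]
  rownames(out) <- NULL
  out
}
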