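# Chemical-shift-based structural calls: secondary structure from
# Calpha/Cbeta shifts against literature class statistics, glutamate
# protonation state, proline cis/trans isomer from the Cbeta-Cgamma
# separation, secondary-chemical-shift profiles with the
# three-consecutive-residues rule, and CP/INEPT rigidity partitioning.

.new_classification <- function(subject, class, scores, margin, status) {
  structure(list(subject = subject, class = class, scores = scores,
                 margin = margin, status = status),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s: %s (%s; margin %.3g)\n", x$subject,
              if (is.na(x$class)) "-" else x$class, x$status, x$margin))
  invisible(x)
}

#' Classify secondary structure from carbon chemical shifts
#'
#' Scores each structure class by the squared standardised distance
#' summed over the available atoms,
#' \eqn{\sum_a ((\delta_a - \mu_{a,c}) / \sigma_{a,c})^2}, and assigns the
#' lowest-scoring class.  The call is `ambiguous` when the best and
#' runner-up scores differ by at most `tie_tol`, and `unassigned` when the
#' best per-atom mean score exceeds `cutoff` (default 9, i.e. about three
#' standard deviations per atom).
#'
#' @param residue One-letter residue code.
#' @param shifts Named numeric vector of observed shifts (ppm), e.g.
#'   `c(CA = 51.5, CB = 22.8)`.
#' @param tables A [load_reference_tables()] result.
#' @param tie_tol Score-gap tie tolerance (default 0.5).
#' @param cutoff Per-atom score cutoff for `unassigned` (default 9).
#' @param subject Label used in the result (defaults to the residue).
#' @return A `classification_result` with per-class scores.
#' @examples
#' ref <- load_reference_tables()
#' classify_secondary_structure("A", c(CA = 51.5, CB = 22.8), ref)$class
#' @export
classify_secondary_structure <- function(residue, shifts, tables,
                                         tie_tol = 0.5, cutoff = 9,
                                         subject = residue) {
  stopifnot(inherits(tables, "reference_tables"))
  tab <- tables$shifts[tables$shifts$residue == residue, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("residue '", residue, "' absent from the reference table")
  atoms <- intersect(names(shifts), unique(tab$atom))
  if (!length(atoms))
    stop("no observed atom of residue '", residue, "' is in the reference table")
  classes <- c("helix", "sheet", "coil")
  scores <- vapply(classes, function(cl) {
    s <- 0
    for (a in atoms) {
      row <- tab[tab$atom == a & tab$class == cl, , drop = FALSE]
      s <- s + ((shifts[[a]] - row$mean_ppm[1]) / row$sd_ppm[1])^2
    }
    s
  }, 0)
  ord <- order(scores)
  best <- classes[ord[1]]
  margin <- scores[ord[2]] - scores[ord[1]]
  status <- if (margin <= tie_tol) "ambiguous"
            else if (scores[ord[1]] / length(atoms) > cutoff) "unassigned"
            else "assigned"
  .new_classification(subject, if (status == "assigned") best else NA_character_,
                      scores, margin, status)
}

#' Classify glutamate protonation state
#'
#' Nearest reference Cgamma/Cdelta pair in Euclidean ppm distance; the
#' deprotonated side chain is the more deshielded one at Cdelta.  With
#' `cd_only = TRUE` only the (dominant) Cdelta coordinate is used.
#'
#' @param cg,cd Observed Cgamma and Cdelta shifts (ppm); `cg` may be `NA`
#'   with `cd_only = TRUE`.
#' @param tables A [load_reference_tables()] result.
#' @param tie_tol Distance-gap (ppm) under which the call is ambiguous.
#' @param cd_only Use only the Cdelta shift.
#' @param subject Result label.
#' @return A `classification_result` with per-state distances as scores.
#' @export
classify_glu_protonation <- function(cg, cd, tables, tie_tol = 0.2,
                                     cd_only = FALSE, subject = "Glu") {
  stopifnot(inherits(tables, "reference_tables"))
  if (!cd_only && (is.na(cg) || is.na(cd)))
    stop("both 'cg' and 'cd' are required unless cd_only = TRUE")
  prot <- tables$protonation
  ref <- function(state, atom)
    prot$shift_ppm[prot$state == state & prot$atom == atom]
  dist_to <- function(state) {
    dd <- cd - ref(state, "CD")
    if (cd_only) abs(dd)
    else sqrt((cg - ref(state, "CG"))^2 + dd^2)
  }
  scores <- c(deprotonated = dist_to("deprotonated"),
              protonated = dist_to("protonated"))
  margin <- abs(scores[1] - scores[2])
  status <- if (margin <= tie_tol) "ambiguous" else "assigned"
  best <- names(scores)[which.min(scores)]
  .new_classification(subject, if (status == "assigned") best else NA_character_,
                      scores, unname(margin), status)
}

#' Classify proline cis/trans isomer from Cbeta and Cgamma shifts
#'
#' The discriminator is the separation
#' \eqn{\Delta_{\beta\gamma} = \delta(C\beta) - \delta(C\gamma)}: cis
#' prolines show a markedly larger separation (~9.6 ppm) than trans
#' (~4.5 ppm).  Values below the threshold call trans, above cis, exactly
#' at the threshold ambiguous.
#'
#' @param cb,cg Observed Cbeta and Cgamma shifts (ppm).
#' @param tables A [load_reference_tables()] result (supplies the
#'   threshold, default 7.0 ppm).
#' @param threshold Override the packaged threshold.
#' @param subject Result label.
#' @return A `classification_result`; `scores` holds the observed
#'   separation and the threshold.
#' @export
classify_pro_isomer <- function(cb, cg, tables = NULL, threshold = NULL,
                                subject = "Pro") {
  if (is.null(threshold)) {
    threshold <- if (!is.null(tables)) tables$proline$delta_bg_threshold_ppm
                 else 7.0
  }
  dbg <- cb - cg
  class <- if (dbg < threshold) "trans" else if (dbg > threshold) "cis"
           else NA_character_
  status <- if (is.na(class)) "ambiguous" else "assigned"
  .new_classification(subject, class,
                      c(delta_bg = dbg, threshold = threshold),
                      abs(dbg - threshold), status)
}

#' Trans-to-cis population ratio from slice integrals
#'
#' @param trans_integral,cis_integral Non-negative integrals of the
#'   isomer-resolved resonances.
#' @param trans_sigma,cis_sigma Optional integral uncertainties; when
#'   given, the ratio uncertainty is propagated to first order.
#' @return List with `ratio` (trans:cis), `infinite` flag (cis integral
#'   zero), and `sigma` (NA without input uncertainties).
#' @export
cis_trans_ratio <- function(trans_integral, cis_integral,
                            trans_sigma = NA_real_, cis_sigma = NA_real_) {
  if (trans_integral < 0 || cis_integral < 0)
    stop("integrals must be non-negative")
  if (cis_integral == 0)
    return(list(ratio = Inf, infinite = TRUE, sigma = NA_real_))
  ratio <- trans_integral / cis_integral
  sigma <- if (!is.na(trans_sigma) && !is.na(cis_sigma))
    ratio * sqrt((trans_sigma / trans_integral)^2 +
                 (cis_sigma / cis_integral)^2)
  else NA_real_
  list(ratio = ratio, infinite = FALSE, sigma = sigma)
}

#' Secondary chemical-shift profile with the three-consecutive rule
#'
#' Computes \eqn{\Delta\delta} = observed - (context-corrected random
#' coil) per atom and residue, combines Calpha and Cbeta as
#' \eqn{\Delta\delta(C\alpha) - \Delta\delta(C\beta)} when both are
#' present (the two atoms shift in opposite senses with structure), and
#' calls a helix (positive) or strand (negative) element only for runs of
#' at least `min_run` consecutive residues of the same sign.
#'
#' @param observed Data frame with columns `position` (global position in
#'   the construct), `residue`, `atom`, `shift_ppm`.
#' @param construct A [build_construct()] result (resolves neighbour
#'   context for random-coil corrections).
#' @param tables A [load_reference_tables()] result.
#' @param min_run Minimum run length for an element call (default 3).
#' @return Data frame per position: `position`, `residue`, `delta_ca`,
#'   `delta_cb`, `combined`, `sign`, `element` (`"helix"`, `"strand"`,
#'   `"none"`).
#' @export
secondary_shift_profile <- function(observed, construct, tables, min_run = 3) {
  stopifnot(inherits(construct, "repeat_construct"),
            inherits(tables, "reference_tables"))
  seq_chars <- strsplit(construct$full_sequence, "")[[1]]
  positions <- sort(unique(observed$position))
  out <- data.frame(position = positions,
                    residue = seq_chars[positions],
                    delta_ca = NA_real_, delta_cb = NA_real_,
                    combined = NA_real_, sign = 0L,
                    element = "none", stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    pos <- out$position[r]; res <- out$residue[r]
    context <- if (pos > 1 && seq_chars[pos - 1] == "P") "prePro" else "none"
    rows <- observed[observed$position == pos, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      atom <- rows$atom[k]
      if (rows$residue[k] != res)
        stop(sprintf("observed residue '%s' at position %d does not match construct '%s'",
                     rows$residue[k], pos, res))
      rc <- random_coil_shift(tables, res, atom,
                              if (atom == "CA") context else "none")
      dd <- rows$shift_ppm[k] - rc
      if (atom == "CA") out$delta_ca[r] <- dd
      if (atom == "CB") out$delta_cb[r] <- dd
    }
    out$combined[r] <- if (!is.na(out$delta_ca[r]) && !is.na(out$delta_cb[r]))
      out$delta_ca[r] - out$delta_cb[r]
    else if (!is.na(out$delta_ca[r])) out$delta_ca[r]
    else if (!is.na(out$delta_cb[r])) -out$delta_cb[r]
    else NA_real_
    out$sign[r] <- sign(out$combined[r])
  }
  # element calls: runs of >= min_run consecutive positions, same nonzero sign
  if (nrow(out)) {
    run_start <- 1L
    flush <- function(from, to) {
      if (to - from + 1L >= min_run && out$sign[from] != 0) {
        lab <- if (out$sign[from] > 0) "helix" else "strand"
        out$element[from:to] <<- lab
      }
    }
    for (r in seq_len(nrow(out))) {
      if (r == 1L) next
      contiguous <- out$position[r] == out$position[r - 1L] + 1L
      same_sign <- out$sign[r] == out$sign[r - 1L]
      if (!contiguous || !same_sign) {
        flush(run_start, r - 1L)
        run_start <- r
      }
    }
    flush(run_start, nrow(out))
  }
  out
}

#' Partition components into rigid/mobile classes from CP and INEPT peaks
#'
#' Presence/absence logic mirroring qualitative dynamic spectral editing:
#' a predicted component matched (within tolerance) only in the CP peak
#' list is `rigid`, only in the INEPT list `mobile`, in both `both`, in
#' neither `unobserved`.
#'
#' @param cp_peaks,inept_peaks Peak data frames (see
#'   [match_cross_peaks()]) from matched experiments on the same sample.
#' @param predicted Data frame with `label` and position columns.
#' @param tolerance Matching tolerance in ppm.
#' @return Data frame: `label`, `in_cp`, `in_inept`, `call`.
#' @export
rigidity_partition <- function(cp_peaks, inept_peaks, predicted,
                               tolerance = 0.3) {
  seen <- function(peaks) {
    if (is.null(peaks) || nrow(peaks) == 0L)
      return(rep(FALSE, nrow(predicted)))
    m <- match_cross_peaks(peaks, predicted, tolerance)
    m$within_tolerance
  }
  in_cp <- seen(cp_peaks)
  in_inept <- seen(inept_peaks)
  call <- ifelse(in_cp & in_inept, "both",
          ifelse(in_cp, "rigid",
          ifelse(in_inept, "mobile", "unobserved")))
  data.frame(label = predicted$label, in_cp = in_cp, in_inept = in_inept,
             call = call, stringsAsFactors = FALSE)
}
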