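#' Define a transmembrane helix
#'
#' Declares one TM helix for Ballesteros-Weinstein (BW) generic numbering:
#' an inclusive residue range, the anchor residue and the generic position
#' assigned to it. In the BW scheme the most conserved residue of helix H is
#' position H.50 and neighbours are numbered consecutively; anchoring at a
#' position other than 50 is allowed (e.g. a helix anchored directly at its
#' x.48 tryptophan).
#'
#' @param helix_id Integer 1-8 (TM1-TM7, H8).
#' @param start,end First and last residue sequence number (inclusive).
#' @param anchor_seq Residue sequence number of the anchor.
#' @param anchor_position Two-digit generic position of the anchor
#'   (default 50).
#' @param intracellular_end Which end of the range faces the cytoplasm
#'   (`"start"` or `"end"`); used by helix-end distance analyses.
#' @return A `helix_def` list.
#' @export
helix_def <- function(helix_id, start, end, anchor_seq,
                      anchor_position = 50,
                      intracellular_end = c("end", "start")) {
  intracellular_end <- match.arg(intracellular_end)
  helix_id <- as.integer(helix_id)
  if (is.na(helix_id) || helix_id < 1 || helix_id > 8)
    rlang::abort("helix_id must be in 1..8", class = "gpcrtraj_definition_error")
  if (start > end)
    rlang::abort("helix start must not exceed end", class = "gpcrtraj_definition_error")
  if (anchor_seq < start || anchor_seq > end)
    rlang::abort("anchor residue must lie within the helix range",
                 class = "gpcrtraj_definition_error")
  structure(list(helix_id = helix_id, start = as.integer(start),
                 end = as.integer(end), anchor_seq = as.integer(anchor_seq),
                 anchor_position = as.integer(anchor_position),
                 intracellular_end = intracellular_end),
            class = "helix_def")
}

#' @export
print.helix_def <- function(x, ...) {
  cat(sprintf("<helix_def> TM%d %d-%d, anchor %d = %d.%02d, intracellular %s\n",
              x$helix_id, x$start, x$end, x$anchor_seq, x$helix_id,
              x$anchor_position, x$intracellular_end))
  invisible(x)
}

#' Assign Ballesteros-Weinstein indices
#'
#' Maps every residue of each helix to its generic BW index: the anchor gets
#' `anchor_position` and position increments by one per residue, so residue
#' `r` gets `anchor_position + (r - anchor_seq)`.
#'
#' @param helices A `helix_def` or list of them.
#' @return Tibble with columns `residue_seq`, `helix_id`, `position`, and
#'   the rendered string `bw` ("H.PP").
#' @export
assign_bw <- function(helices) {
  if (inherits(helices, "helix_def")) helices <- list(helices)
  if (!length(helices) || !all(purrr::map_lgl(helices, inherits, "helix_def")))
    rlang::abort("`helices` must be helix_def objects", class = "gpcrtraj_definition_error")
  rng <- purrr::map(helices, function(h) h$start:h$end)
  allres <- unlist(rng)
  if (anyDuplicated(allres))
    rlang::abort("helix residue ranges overlap", class = "gpcrtraj_definition_error")
  out <- purrr::map_dfr(helices, function(h) {
    seqs <- h$start:h$end
    pos <- h$anchor_position + (seqs - h$anchor_seq)
    if (any(pos < 1 | pos > 99))
      rlang::abort(sprintf("TM%d produces BW positions outside 1..99", h$helix_id),
                   class = "gpcrtraj_range_error")
    tibble::tibble(residue_seq = seqs, helix_id = h$helix_id, position = pos)
  })
  out$bw <- sprintf("%d.%02d", out$helix_id, out$position)
  dplyr::arrange(out, .data$residue_seq)
}

#' Reconstructed S1P1 helix definitions
#'
#' Transmembrane helix ranges and BW anchors for the sphingosine
#' 1-phosphate receptor 1. The anchors are the conserved residues
#' N63 (1.50), D91 (2.50), 3.50 at residue 142, 5.50 at 213, W269
#' anchored directly at 6.48, and P308 (7.50). The helix boundaries are
#' reconstructed — chosen to be mutually disjoint and consistent with
#' every published residue/superscript pair for this receptor — rather
#' than taken from an annotation, and should be overridden with
#' structure-derived ranges when available.
#'
#' @return List of [helix_def()] objects (TM1-TM3, TM5-TM7).
#' @export
s1p1_helices <- function() {
  list(
    helix_def(1, 44, 73, anchor_seq = 63, anchor_position = 50),
    helix_def(2, 80, 107, anchor_seq = 91, anchor_position = 50),
    helix_def(3, 113, 147, anchor_seq = 142, anchor_position = 50),
    helix_def(5, 190, 223, anchor_seq = 213, anchor_position = 50),
    helix_def(6, 245, 281, anchor_seq = 269, anchor_position = 48),
    helix_def(7, 290, 313, anchor_seq = 308, anchor_position = 50)
  )
}

#' Resolve a BW index to a residue number
#'
#' Inverse of [assign_bw()]: `lookup_bw(assign_bw(h), "7.50")` returns the
#' anchor residue of TM7.
#'
#' @param bw_map Tibble from [assign_bw()].
#' @param index BW index string such as `"6.48"` (position zero-padded or
#'   not).
#' @return Residue sequence number (integer).
#' @export
lookup_bw <- function(bw_map, index) {
  if (!grepl("^[0-9]\\.[0-9]{1,2}$", index))
    rlang::abort(paste0("malformed BW index: '", index, "'"),
                 class = "gpcrtraj_lookup_error")
  parts <- as.integer(strsplit(index, ".", fixed = TRUE)[[1]])
  hit <- bw_map$residue_seq[bw_map$helix_id == parts[1] & bw_map$position == parts[2]]
  if (length(hit) != 1)
    rlang::abort(paste0("BW index not in map: ", index), class = "gpcrtraj_lookup_error")
  hit
}
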