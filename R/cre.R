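# Sequence-level classification of the charge-relay conformational
# regulation element (CRE) across a pyrin-domain family alignment: an
# acidic/basic/acidic anchor triad (NLRP14 numbering 26/84/86, with the
# conserved Met82 marking the motif) predicts closed-monomer propensity;
# a broken triad predicts open-dimer propensity.

.DEFAULT_ANCHORS <- c(E = 26, M = 82, central = 84, D = 86)
.GAP_CHARS <- c("-", ".")

#' Construct an alignment object
#'
#' @param ids unique sequence identifiers.
#' @param seqs gapped sequences (equal length, gap characters `-` or `.`).
#' @return object of class `cre_alignment` with `ids`, `seqs` (gaps
#'   normalized to `-`, upper case) and `n_columns`.
#' @export
new_alignment <- function(ids, seqs) {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (length(ids) == 0) stop("empty alignment")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr(".", "-", seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: row '", ids[which(widths != widths[1])[1]],
         "' has width ", widths[widths != widths[1]][1],
         " (expected ", widths[1], ")")
  bad <- grepl(sprintf("[^%sX*-]", paste(names(.AA1TO3), collapse = "")), seqs)
  if (any(bad))
    stop("non-amino-acid characters in row '", ids[which(bad)[1]], "'")
  structure(list(ids = ids, seqs = seqs, n_columns = widths[1]),
            class = "cre_alignment")
}

#' @export
print.cre_alignment <- function(x, ...) {
  cat("Alignment:", length(x$ids), "sequences x", x$n_columns, "columns\n")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' @param path file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return a [new_alignment()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) stop("failed to parse ", format, " alignment '",
                             path, "': ", conditionMessage(e), call. = FALSE)
  )
  seqs <- as.character(Biostrings::unmasked(aln))
  new_alignment(names(seqs), unname(seqs))
}

#' Map author residue numbers of a reference row to alignment columns
#'
#' @param a a `cre_alignment`.
#' @param reference_id id of the numbering-reference row (NLRP14 in the
#'   default usage).
#' @param anchors named integer vector of residue numbers in the ungapped
#'   reference sequence (default `c(E = 26, M = 82, central = 84, D = 86)`).
#' @param reference_start author number of the first reference residue
#'   (default 1).
#' @return named integer vector of 1-based alignment columns: the column of
#'   the k-th non-gap character of the reference row, an order-preserving
#'   bijection.
#' @export
map_anchor_columns <- function(a, reference_id, anchors = .DEFAULT_ANCHORS,
                               reference_start = 1) {
  stopifnot(inherits(a, "cre_alignment"))
  ri <- match(reference_id, a$ids)
  if (is.na(ri)) stop("reference row '", reference_id, "' not in alignment")
  ch <- strsplit(a$seqs[ri], "")[[1]]
  non_gap <- which(!(ch %in% .GAP_CHARS))
  k <- anchors - reference_start + 1
  if (any(k < 1 | k > length(non_gap)))
    stop("anchor(s) beyond the ungapped reference length (",
         length(non_gap), " residues): ",
         paste(anchors[k < 1 | k > length(non_gap)], collapse = ", "))
  structure(non_gap[k], names = names(anchors))
}

#' Classify charge-relay intactness across an alignment
#'
#' @param a a `cre_alignment`.
#' @param anchor_columns named columns from [map_anchor_columns()]; must
#'   include `E`, `central` and `D` (an `M` column, if present, is reported
#'   but does not affect the call).
#' @return data.frame of class `cre_profiles`, one row per sequence:
#'   the residues at the anchor columns, `bridge_status` (`"intact"` iff the
#'   E anchor is E/D, the central anchor is R/K and the D anchor is D/E;
#'   `"broken"` otherwise, with `note = "gap"` when a gap sits at an anchor)
#'   and `prediction` (`"closed-propensity"` iff intact, else
#'   `"open-propensity"`).
#' @details Chemically conservative substitutions (E/D acidic, R/K basic) are
#'   accepted as intact.
#' @export
classify_cre <- function(a, anchor_columns) {
  stopifnot(inherits(a, "cre_alignment"))
  need <- c("E", "central", "D")
  if (!all(need %in% names(anchor_columns)))
    stop("anchor_columns must name E, central and D")
  if (any(anchor_columns < 1 | anchor_columns > a$n_columns))
    stop("anchor column outside alignment width")
  at <- function(col) substr(a$seqs, col, col)
  rE <- at(anchor_columns[["E"]])
  rC <- at(anchor_columns[["central"]])
  rD <- at(anchor_columns[["D"]])
  rM <- if ("M" %in% names(anchor_columns)) at(anchor_columns[["M"]])
  else rep(NA_character_, length(rE))
  gap <- rE %in% .GAP_CHARS | rC %in% .GAP_CHARS | rD %in% .GAP_CHARS
  intact <- !gap & rE %in% c("E", "D") & rC %in% c("R", "K") &
    rD %in% c("D", "E")
  out <- data.frame(
    sequence_id = a$ids,
    residue_at_E_anchor = rE, residue_at_M82 = rM,
    residue_at_central = rC, residue_at_D_anchor = rD,
    bridge_status = ifelse(intact, "intact", "broken"),
    note = ifelse(gap, "gap", ""),
    prediction = ifelse(intact, "closed-propensity", "open-propensity"),
    stringsAsFactors = FALSE)
  class(out) <- c("cre_profiles", "data.frame")
  out
}

#' Family report of charge-relay classifications
#'
#' @param profiles a [classify_cre()] result.
#' @param path optional TSV output path.
#' @return list of class `cre_family_report`: the profile `table` (input
#'   order preserved) and `counts` (named: intact, broken).
#' @export
family_report <- function(profiles, path = NULL) {
  stopifnot(inherits(profiles, "cre_profiles"))
  if (nrow(profiles) < 1) stop("no profiles to report")
  counts <- c(intact = sum(profiles$bridge_status == "intact"),
              broken = sum(profiles$bridge_status == "broken"))
  if (!is.null(path)) {
    utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  structure(list(table = profiles, counts = counts),
            class = "cre_family_report")
}

#' @export
print.cre_family_report <- function(x, ...) {
  cat("CRE family report:", x$counts[["intact"]], "intact /",
      x$counts[["broken"]], "broken charge relay(s)\n")
  print(x$table[, c("sequence_id", "residue_at_E_anchor",
                    "residue_at_central", "residue_at_D_anchor",
                    "bridge_status", "prediction")])
  invisible(x)
}
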