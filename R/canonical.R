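# Canonical SMILES via OpenBabel (ChemmineOB). Atom maps are stripped and
# fragment order normalized, so two structures are identical iff their
# canonical strings are equal.

.canon_cache <- new.env(parent = emptyenv())

canonical_error <- function(msg) {
  stop(errorCondition(msg, class = c("rxn_canonical_error", "error")))
}

#' Canonicalize a SMILES string
#'
#' Converts to OpenBabel canonical SMILES, strips atom-map ids, and sorts
#' dot-separated fragments lexicographically so the result is independent of
#' input atom and fragment order. Results are memoized per session.
#'
#' @param smiles A SMILES string (may contain atom maps and `.` fragments).
#' @return The canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  key <- smiles
  hit <- .canon_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  out <- gsub("[ \t\r\n]+", "", out)
  if (!nzchar(out))
    canonical_error(sprintf("sanitization/canonicalization failed for '%s'", smiles))
  # radix = byte order: fragment ordering must not depend on the locale
  parts <- sort(strsplit(out, ".", fixed = TRUE)[[1]], method = "radix")
  res <- paste(parts, collapse = ".")
  assign(key, res, envir = .canon_cache)
  res
}

#' Exact-match comparison of two product SMILES
#'
#' Two predictions denote the same product iff their canonical, map-stripped
#' SMILES strings are equal. By default stereochemistry markers are removed
#' before comparison.
#'
#' @param predicted,recorded SMILES strings.
#' @param ignore_stereo Strip stereo bond/atom markers before comparing.
#' @return `TRUE` or `FALSE`.
#' @export
exact_match <- function(predicted, recorded, ignore_stereo = TRUE) {
  strip <- function(s) if (ignore_stereo) gsub("[/\\\\]|@{1,2}", "", s) else s
  identical(canonical_smiles(strip(predicted)), canonical_smiles(strip(recorded)))
}

#' Canonical product SMILES from an edited molecular graph
#'
#' Applies the fragment-retention policy and returns the canonical,
#' map-stripped SMILES of the product. Under the default `"edit_atoms"`
#' policy only connected components containing at least one atom that
#' participated in a graph edit are retained; `"all"` keeps every fragment.
#'
#' @param graph A `mol_graph`, typically from [apply_edits()].
#' @param edit_atoms Integer atom indices that participated in the edits
#'   (required for the default policy).
#' @param keep_fragments `"edit_atoms"` (default) or `"all"`.
#' @return Canonical SMILES string.
#' @export
canonical_product <- function(graph, edit_atoms = integer(0),
                              keep_fragments = c("edit_atoms", "all")) {
  keep_fragments <- match.arg(keep_fragments)
  g <- graph
  if (keep_fragments == "edit_atoms") {
    if (length(edit_atoms) == 0L)
      canonical_error("edit_atoms required under the 'edit_atoms' retention policy")
    keep_sp <- unique(g$species[edit_atoms])
    g <- mol_subgraph(g, which(g$species %in% keep_sp))
  }
  canonical_smiles(graph_to_smiles(g, include_maps = FALSE))
}
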