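#' The canonical 24-variable FOCM/TS metabolite panel
#'
#' Ordered names of the 24 folate-dependent one-carbon metabolism (FOCM) and
#' transsulfuration (TS) variables measured per participant: methylation-cycle
#' metabolites (methionine, SAM, SAH and their ratio), DNA methylation and
#' oxidative-damage markers, and the glutathione/cysteine redox panel. Four
#' variables are ratios derived from other panel members and are recomputed
#' during validation.
#'
#' @return Character vector of length 24, the canonical variable names in
#'   canonical order.
#' @export
#' @examples
#' metabolite_panel()
metabolite_panel <- function() {
  c("Methionine", "SAM", "SAH", "SAM/SAH", "% DNA methylation", "8-OHG",
    "Adenosine", "Homocysteine", "Cysteine", "Glu.-Cys.", "Cys.-Gly.",
    "tGSH", "fGSH", "GSSG", "fGSH/GSSG", "tGSH/GSSG", "Chlorotyrosine",
    "Nitrotyrosine", "Tyrosine", "Tryptophane", "fCystine", "fCysteine",
    "fCystine/fCysteine", "% oxidized glutathione")
}

#' Ratio variables of the panel and their components
#'
#' The panel carries four variables that are exact ratios of two other panel
#' members. They are validated (and, in synthetic data, generated) by
#' recomputation from their components, which also reproduces the near-exact
#' collinearity the real panel exhibits.
#'
#' @return Named list; each element is \code{c(numerator, denominator)} and the
#'   element name is the ratio variable.
#' @export
panel_ratios <- function() {
  list(
    "SAM/SAH"            = c("SAM", "SAH"),
    "fGSH/GSSG"          = c("fGSH", "GSSG"),
    "tGSH/GSSG"          = c("tGSH", "GSSG"),
    "fCystine/fCysteine" = c("fCystine", "fCysteine")
  )
}

#' Base (non-ratio) variables of a panel
#' @param panel character vector of panel names (default full 24-panel).
#' @return Character vector of panel names that are not derived ratios.
#' @export
panel_base_variables <- function(panel = metabolite_panel()) {
  setdiff(panel, names(panel_ratios()))
}

# Canonical key for alias matching: case-, whitespace- and
# punctuation-insensitive. "pct" is folded to "percent" so headers like
# "pct_dna_methylation" resolve.
.panel_key <- function(x) {
  x <- tolower(x)
  x <- gsub("%", "percent", x, fixed = TRUE)
  x <- gsub("pct", "percent", x, fixed = TRUE)
  gsub("[^a-z0-9]+", "", x)
}

#' Resolve arbitrary column headers to canonical panel names
#'
#' Matching is insensitive to case, whitespace and punctuation, and an explicit
#' alias map can supplement it (supplementary-file headers are not standardized
#' across sources).
#'
#' @param headers character vector of column names as found in a file.
#' @param aliases optional named character vector/list mapping a raw header to
#'   a canonical panel name (or to "cohort"/"id"/"vineland").
#' @return Named character vector: for each input header the canonical name it
#'   resolved to, or \code{NA} if unresolved.
#' @export
resolve_panel_names <- function(headers, aliases = NULL) {
  canon <- c(metabolite_panel(), "cohort", "id", "vineland")
  keys <- .panel_key(canon)
  out <- canon[match(.panel_key(headers), keys)]
  if (!is.null(aliases)) {
    aliases <- unlist(aliases)
    hit <- match(headers, names(aliases))
    out[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  }
  names(out) <- headers
  out
}
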