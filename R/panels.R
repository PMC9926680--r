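## Gene-panel registry: one in-silico panel per disease macro-category plus
## the "kidneyome" super-panel (exact union of the subpanels), and the rule
## deciding when a negative subpanel analysis escalates to the super-panel.

#' Construct a gene panel
#'
#' @param name panel name.
#' @param category the macro-category the panel serves, or `"kidneyome"`.
#' @param entries data.frame with columns `gene`, `moi` (one of
#'   [INHERITANCE_MODES]), `chromosome`. A gene with dual inheritance is
#'   entered once per mode; otherwise `(gene, moi)` rows must be unique.
#' @param version panel version string.
#' @return list of class `gene_panel`.
#' @export
gene_panel <- function(name, category, entries, version = "1") {
  stopifnot(is.data.frame(entries),
            all(c("gene", "moi", "chromosome") %in% names(entries)))
  if (!category %in% c(MACRO_CATEGORIES, "kidneyome"))
    stop("unknown panel category: ", category)
  bad <- setdiff(unique(entries$moi), INHERITANCE_MODES)
  if (length(bad)) stop("unknown inheritance mode(s): ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(entries[, c("gene", "moi")]))
    stop("duplicate (gene, moi) entries in panel ", name)
  structure(list(name = name, category = category,
                 entries = entries[, c("gene", "moi", "chromosome")],
                 version = as.character(version)),
            class = "gene_panel")
}

#' @method print gene_panel
#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel %s (%s), %d entries, v%s>\n", x$name, x$category,
              nrow(x$entries), x$version))
  invisible(x)
}

#' Build the kidneyome super-panel as the union of subpanels
#'
#' @param registry list of `gene_panel` objects (the subpanels).
#' @param version version string for the derived panel.
#' @return a `gene_panel` with category `"kidneyome"` whose entries are the
#'   deduplicated union of all subpanel entries.
#' @export
kidneyome_panel <- function(registry, version = "1") {
  subs <- Filter(function(p) p$category != "kidneyome", registry)
  entries <- unique(do.call(rbind, lapply(subs, `[[`, "entries")))
  entries <- entries[order(entries$gene, entries$moi), , drop = FALSE]
  rownames(entries) <- NULL
  gene_panel("kidneyome", "kidneyome", entries, version)
}

#' Select the analysis panel for a patient
#'
#' @param patient a single-row [patient_records()] table (or list with
#'   `macro_category`).
#' @param registry list of `gene_panel` objects, one per macro-category
#'   (plus, optionally, the kidneyome).
#' @return the `gene_panel` matching the patient's macro-category.
#' @export
select_panel <- function(patient, registry) {
  cat_ <- patient$macro_category
  stopifnot(length(cat_) == 1L)
  hit <- Filter(function(p) p$category == cat_, registry)
  if (!length(hit))
    stop("configuration error: no panel registered for macro-category '",
         cat_, "'")
  hit[[1]]
}

#' Decide escalation from subpanel to kidneyome
#'
#' Analysis is widened to the kidneyome super-panel only when the subpanel
#' result is negative and the clinical phenotype is either not clearly
#' indicative or overlaps several disease categories. All three flags are
#' clinician-supplied, never inferred from the data.
#'
#' @param subpanel_negative,phenotype_unclear,phenotype_overlapping logicals.
#' @return logical.
#' @export
should_escalate <- function(subpanel_negative, phenotype_unclear,
                            phenotype_overlapping) {
  stopifnot(is.logical(subpanel_negative), is.logical(phenotype_unclear),
            is.logical(phenotype_overlapping),
            !anyNA(c(subpanel_negative, phenotype_unclear,
                     phenotype_overlapping)))
  subpanel_negative & (phenotype_unclear | phenotype_overlapping)
}

#' Restrict calls to a panel's genes
#'
#' @param calls a [variant_calls()] table.
#' @param panel a `gene_panel`.
#' @return the rows of `calls` whose `gene` is a panel entry, input order
#'   preserved.
#' @export
restrict_to_panel <- function(calls, panel) {
  calls[calls$gene %in% panel$entries$gene, , drop = FALSE]
}

#' Look up the inheritance mode(s) of a gene in a panel
#'
#' @param panel a `gene_panel`.
#' @param gene gene symbol.
#' @return character vector of modes (length > 1 for dual-inheritance genes;
#'   `"NA"` when the gene is absent or has no curated mode).
#' @export
panel_moi <- function(panel, gene) {
  m <- panel$entries$moi[panel$entries$gene == gene]
  if (!length(m)) "NA" else m
}

#' Read a panel registry from TSV
#'
#' Expects columns `gene`, `moi`, `chromosome`, `category`, `panel_version`;
#' one panel is built per category and the kidneyome is derived as their
#' union.
#'
#' @param path TSV file.
#' @return list of `gene_panel` objects keyed by category, including
#'   `"kidneyome"`.
#' @export
read_panel_registry <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "moi", "chromosome", "category", "panel_version")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("panel TSV lacks columns: ",
                         paste(miss, collapse = ", "))
  registry <- lapply(split(tab, tab$category), function(g)
    gene_panel(g$category[1], g$category[1],
               g[, c("gene", "moi", "chromosome")], g$panel_version[1]))
  registry <- unname(registry)
  c(registry, list(kidneyome_panel(registry)))
}

#' Write a panel registry to TSV
#'
#' @param registry list of `gene_panel` objects; the kidneyome (derivable) is
#'   skipped.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_panel_registry <- function(registry, path) {
  subs <- Filter(function(p) p$category != "kidneyome", registry)
  tab <- do.call(rbind, lapply(subs, function(p) {
    e <- p$entries
    e$category <- p$category
    e$panel_version <- p$version
    e
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
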