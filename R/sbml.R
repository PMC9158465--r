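#' Read species initial conditions from an SBML file
#'
#' Convenience cross-check: extracts species identifiers and their initial
#' concentrations (or amounts) from an SBML Level 2 document, e.g. a model
#' downloaded from the BioModels repository. Used only for comparing
#' initial conditions against the package defaults; nothing in the package
#' requires it.
#'
#' @param path path to an SBML (XML) file.
#' @return A data frame with columns `id`, `name`, `compartment`,
#'   `initial` (concentration or amount, as stored).
#' @export
sbml_initial_conditions <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("sbml_initial_conditions() needs the 'xml2' package")
  }
  stopifnot(file.exists(path))
  doc <- xml2::read_xml(path)
  species <- xml2::xml_find_all(doc, ".//*[local-name() = 'species']")
  if (length(species) == 0) stop("no species elements in ", path)
  get_attr <- function(a) xml2::xml_attr(species, a)
  init <- suppressWarnings(as.numeric(get_attr("initialConcentration")))
  amt <- suppressWarnings(as.numeric(get_attr("initialAmount")))
  init[is.na(init)] <- amt[is.na(init)]
  data.frame(id = get_attr("id"),
             name = get_attr("name"),
             compartment = get_attr("compartment"),
             initial = init)
}
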