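# RDF/RDFS/OWL/XSD vocabulary IRIs used across the readers and writers.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"

rdf_iri  <- function(x) paste0(RDF_NS, x)
rdfs_iri <- function(x) paste0(RDFS_NS, x)
owl_iri  <- function(x) paste0(OWL_NS, x)
xsd_iri  <- function(x) paste0(XSD_NS, x)

BASE_PREFIXES <- c(
  rdf  = RDF_NS,
  rdfs = RDFS_NS,
  owl  = OWL_NS,
  xsd  = XSD_NS
)

OBO_NS <- "http://purl.obolibrary.org/obo/"

#' The axiom types this package can verbalize
#'
#' Returns the names of the 14 OWL 2 axiom types supported by the
#' verbalization templates. Axioms of any other type encountered while
#' loading an ontology are counted but not returned.
#'
#' @return A character vector of 14 axiom type names.
#' @export
#' @examples
#' owl_supported_types()
owl_supported_types <- function() {
  c(
    "SubClassOf", "EquivalentClasses", "DisjointClasses", "ClassAssertion",
    "ObjectPropertyDomain", "ObjectPropertyRange",
    "DataPropertyDomain", "DataPropertyRange",
    "SymmetricObjectProperty", "FunctionalObjectProperty",
    "FunctionalDataProperty",
    "ObjectPropertyAssertion", "DataPropertyAssertion",
    "DifferentIndividuals"
  )
}

# single-line whitespace normalisation used on every emitted sentence
squish <- function(x) {
  x <- gsub("\\s+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

# local fragment of an IRI: text after the last '#' or '/'
iri_fragment <- function(iri) {
  sub(".*[#/]", "", iri)
}
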