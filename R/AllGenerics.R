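#' @rdname SpidroinSet
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname SpidroinSet
#' @export
setGeneric("speciesTags", function(x) standardGeneric("speciesTags"))

#' @rdname SpidroinSet
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname SpidroinSet
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname SpidroinSet
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname DomainLibrary
#' @export
setGeneric("domainKinds", function(x) standardGeneric("domainKinds"))

#' @rdname MotifCatalog
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname MotifCatalog
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname MotifCatalog
#' @export
setGeneric("motifPatterns", function(x) standardGeneric("motifPatterns"))
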