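#' @rdname Pedigree-class
#' @param object,x a `Pedigree`, `GenotypeData` or `Grm` object.
#' @export
setGeneric("pedRecords", function(object) standardGeneric("pedRecords"))

#' @rdname Pedigree-class
#' @export
setMethod("pedRecords", "Pedigree", function(object) object@records)

#' @rdname Pedigree-class
#' @export
setGeneric("pedIds", function(object) standardGeneric("pedIds"))

#' @rdname Pedigree-class
#' @export
setMethod("pedIds", "Pedigree", function(object) object@records$id)

#' @rdname Pedigree-class
#' @export
setGeneric("founders", function(object) standardGeneric("founders"))

#' Founder ids (both parents unknown)
#' @rdname Pedigree-class
#' @export
setMethod("founders", "Pedigree", function(object) {
  rec <- object@records
  rec$id[is.na(rec$sire) & is.na(rec$dam)]
})

#' Dosage matrix, animals in rows and markers in columns
#'
#' Transposed view of the `"dosage"` assay (the container itself stores
#' markers as rows, Bioconductor-style).
#' @rdname GenotypeData-class
#' @param x a `GenotypeData`.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-class
#' @export
setMethod("dosages", "GenotypeData", function(x)
  t(SummarizedExperiment::assay(x, "dosage")))

#' Marker map as a data.frame (marker, chrom, pos, counted)
#' @rdname GenotypeData-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname GenotypeData-class
#' @export
setMethod("markerInfo", "GenotypeData", function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  data.frame(marker = rownames(x), rd, row.names = NULL,
             stringsAsFactors = FALSE)
})

#' @rdname GenotypeData-class
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname GenotypeData-class
#' @export
setMethod("animalIds", "GenotypeData", function(x) colnames(x))

#' Relationship matrix stored in a Grm
#' @rdname Grm-class
#' @param object a `Grm`.
#' @export
setGeneric("grmMatrix", function(object) standardGeneric("grmMatrix"))

#' @rdname Grm-class
#' @export
setMethod("grmMatrix", "Grm", function(object) object@matrix)

#' Heritability stored in a VarianceComponents fit
#' @rdname VarianceComponents-class
#' @param object a `VarianceComponents`.
#' @export
setGeneric("heritability", function(object) standardGeneric("heritability"))

#' @rdname VarianceComponents-class
#' @export
setMethod("heritability", "VarianceComponents", function(object) object@h2)
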