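# Core containers shared across the pipeline.

#' Construct a phenotype tensor
#'
#' Accession x environment x trait array of environment-level trait values
#' (NA = missing), optionally with replicate-level records and accession
#' group labels (e.g. landrace / cultivar).
#'
#' @param values 3D numeric array, dims (accession, environment, trait),
#'   with dimnames.
#' @param replicates Optional long data frame with columns `accession`,
#'   `environment`, `trait`, `replicate`, `value`.
#' @param groups Optional factor (or character) of group labels named by
#'   accession.
#' @return A `pheno_tensor` object.
#' @export
pheno_tensor <- function(values, replicates = NULL, groups = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (is.null(dimnames(values)) || any(vapply(dimnames(values), is.null,
                                              logical(1)))) {
    stop("`values` must carry full dimnames", call. = FALSE)
  }
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (is.null(names(groups)) ||
        !all(dimnames(values)[[1]] %in% names(groups))) {
      stop("`groups` must be named by accession and cover all accessions",
           call. = FALSE)
    }
    groups <- groups[dimnames(values)[[1]]]
  }
  structure(
    list(values = values, replicates = replicates, groups = groups),
    class = "pheno_tensor"
  )
}

#' @export
print.pheno_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<pheno_tensor> ", d[1], " accessions x ", d[2], " environments x ",
      d[3], " traits; ", sum(!is.na(x$values)), " observed cells",
      if (!is.null(x$replicates)) paste0("; ", nrow(x$replicates),
                                         " replicate records"),
      "\n", sep = "")
  invisible(x)
}

#' Accession, environment and trait names of a phenotype tensor
#' @param pheno A `pheno_tensor`.
#' @return Character vector.
#' @export
accessions <- function(pheno) dimnames(pheno$values)[[1]]

#' @rdname accessions
#' @export
environments <- function(pheno) dimnames(pheno$values)[[2]]

#' @rdname accessions
#' @export
traits <- function(pheno) dimnames(pheno$values)[[3]]

#' Construct a genotype matrix object
#'
#' @param dosage Accession x marker numeric matrix of minor/alternate
#'   allele dosages (0/1/2; inbred panels use 0/2), with dimnames.
#' @param map Data frame with columns `marker`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per marker in column order of `dosage`.
#' @param groups Optional factor of group labels named by accession.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, map = NULL, groups = NULL) {
  stopifnot(is.matrix(dosage))
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("`dosage` must carry row (accession) and column (marker) names",
         call. = FALSE)
  }
  if (is.null(map)) {
    map <- data.frame(marker = colnames(dosage), chrom = NA_character_,
                      pos = NA_integer_, ref = NA_character_,
                      alt = NA_character_, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(map) == ncol(dosage))
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    groups <- groups[rownames(dosage)]
  }
  structure(list(dosage = dosage, map = map, groups = groups),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " accessions x ",
      ncol(x$dosage), " markers\n", sep = "")
  invisible(x)
}
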