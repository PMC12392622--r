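# Readers and writers for the pipeline's table formats.

#' Read / write a weather table as CSV
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping the standard
#'   column names (`environment`, `latitude`, `planting_doy`, `day`,
#'   `tmax`, `tmin`, `prec`, `rh`, `day_length`) to the file's column
#'   names, e.g. `c(tmax = "T2M_MAX")`.
#' @return A validated weather table.
#' @export
read_weather_csv <- function(path, column_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(d)) {
        stop("mapped column ", src, " not found in ", path, call. = FALSE)
      }
      names(d)[names(d) == src] <- std
    }
  }
  validate_weather(d)
  d
}

#' @rdname read_weather_csv
#' @param weather Weather table.
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(weather, path, row.names = FALSE)
  invisible(path)
}

#' Write / read phenotypes as long-format CSV
#'
#' Environment-level values are written as columns `accession`,
#' `environment`, `trait`, `value` (missing cells omitted); replicate-level
#' records, when present, go to a second file with a `replicate` column.
#'
#' @param pheno A [pheno_tensor()].
#' @param path File path for environment-level values.
#' @param replicates_path Optional path for replicate-level records.
#' @export
write_pheno_csv <- function(pheno, path, replicates_path = NULL) {
  v <- pheno$values
  dn <- dimnames(v)
  long <- expand.grid(accession = dn[[1]], environment = dn[[2]],
                      trait = dn[[3]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$value <- as.vector(v)
  long <- long[!is.na(long$value), , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE)
  if (!is.null(replicates_path) && !is.null(pheno$replicates)) {
    utils::write.csv(pheno$replicates, replicates_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_pheno_csv
#' @param groups Optional named group labels to attach.
#' @return `read_pheno_csv()` returns a [pheno_tensor()].
#' @export
read_pheno_csv <- function(path, replicates_path = NULL, groups = NULL) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  acc <- unique(long$accession)
  envs <- unique(long$environment)
  trs <- unique(long$trait)
  v <- array(NA_real_, dim = c(length(acc), length(envs), length(trs)),
             dimnames = list(accession = acc, environment = envs,
                             trait = trs))
  v[cbind(match(long$accession, acc), match(long$environment, envs),
          match(long$trait, trs))] <- long$value
  reps <- if (!is.null(replicates_path)) {
    utils::read.csv(replicates_path, stringsAsFactors = FALSE)
  } else NULL
  pheno_tensor(v, reps, groups)
}

#' Write / read a dosage matrix as CSV
#'
#' Accessions as rows (first column `accession`), markers as columns; an
#' optional `group` column carries landrace/cultivar labels.
#'
#' @param geno A [genotype_matrix()].
#' @param path File path.
#' @export
write_dosage_csv <- function(geno, path) {
  d <- data.frame(accession = rownames(geno$dosage),
                  stringsAsFactors = FALSE)
  if (!is.null(geno$groups)) d$group <- as.character(geno$groups)
  d <- cbind(d, as.data.frame(geno$dosage))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_csv
#' @return `read_dosage_csv()` returns a [genotype_matrix()].
#' @export
read_dosage_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  groups <- NULL
  if ("group" %in% names(d)) {
    groups <- stats::setNames(factor(d$group), d$accession)
  }
  m <- as.matrix(d[, setdiff(names(d), c("accession", "group")),
                   drop = FALSE])
  rownames(m) <- d$accession
  genotype_matrix(m, groups = groups)
}

#' Write genotypes as a VCF
#'
#' Plain-text VCFv4.2 with a GT field, one sample per accession; dosage 0
#' becomes `0/0`, 1 becomes `0/1`, 2 becomes `1/1`, missing `./.`. Group
#' labels travel in a `##accession_groups` header line.
#'
#' @param geno A [genotype_matrix()] with a populated map.
#' @param path File path (uncompressed `.vcf`).
#' @export
write_vcf <- function(geno, path) {
  map <- geno$map
  acc <- rownames(geno$dosage)
  gt_of <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=plastinorm",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(geno$groups)) {
      paste0("##accession_groups=",
             paste(acc, as.character(geno$groups), sep = ":",
                   collapse = ","))
    },
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", acc), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(geno$dosage))) {
    dos <- geno$dosage[, j]
    gt <- ifelse(is.na(dos), "./.", gt_of[dos + 1])
    writeLines(paste(c(as.character(map$chrom[j]), map$pos[j],
                       map$marker[j],
                       ifelse(is.na(map$ref[j]), "A", map$ref[j]),
                       ifelse(is.na(map$alt[j]), "T", map$alt[j]),
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF (GT field to dosage)
#'
#' Uses the vcfR package when available.
#'
#' @param path Path to an uncompressed or gzipped VCF.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), integer(1)))
  }
  dos <- t(apply(gt, 1, count_alt))
  colnames(dos) <- colnames(gt)
  dos <- t(dos)  # accession x marker
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  map <- data.frame(marker = fix$ID, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), ref = fix$REF,
                    alt = fix$ALT, stringsAsFactors = FALSE)
  colnames(dos) <- map$marker
  groups <- NULL
  meta <- v@meta
  gl <- grep("^##accession_groups=", meta, value = TRUE)
  if (length(gl) == 1) {
    pairs <- strsplit(strsplit(sub("^##accession_groups=", "", gl),
                               ",")[[1]], ":")
    groups <- stats::setNames(
      factor(vapply(pairs, `[`, character(1), 2)),
      vapply(pairs, `[`, character(1), 1)
    )
    groups <- groups[rownames(dos)]
  }
  genotype_matrix(dos, map, groups)
}

#' Write reaction-norm fits or simulation truth
#'
#' Fits go to tidy CSV; the simulation ground truth to JSON (requires
#' jsonlite).
#'
#' @param fits A `reaction_norm_fit`.
#' @param path File path.
#' @export
write_fits_csv <- function(fits, path) {
  utils::write.csv(as.data.frame(fits), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fits_csv
#' @param truth A `sim_truth` from [simulate_phenotypes()].
#' @export
write_sim_truth_json <- function(truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing truth JSON requires the jsonlite package", call. = FALSE)
  }
  obj <- list(
    intercept = truth$intercept, slope = truth$slope,
    env_index = as.list(truth$env_index),
    index_center = truth$index_center,
    groups = as.list(stats::setNames(as.character(truth$groups),
                                     names(truth$groups)))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
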