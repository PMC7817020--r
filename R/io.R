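#' Read an annotated variant table
#'
#' Reads a TSV with header columns `variant_id`, `gene`, `consequence`,
#' `maf`, `cadd_phred` (annotation-tool exports with different column
#' names can be adapted via `columnMap`). Empty CADD fields become `NA`
#' (common for frameshift indels).
#'
#' @param path TSV file (gzipped accepted).
#' @param columnMap optional named character vector mapping the required
#'   names to the file's column names, e.g.
#'   `c(gene = "Gene.refGene", cadd_phred = "CADD_phred")`.
#' @return `data.frame` with the five required columns.
#' @export
readVariants <- function(path, columnMap = NULL) {
  tab <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, na.strings = c("NA", ".", "")
  )
  need <- c("variant_id", "gene", "consequence", "maf", "cadd_phred")
  if (!is.null(columnMap)) {
    for (nm in names(columnMap)) {
      names(tab)[names(tab) == columnMap[[nm]]] <- nm
    }
  }
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  }
  tab$maf <- as.numeric(tab$maf)
  tab$cadd_phred <- as.numeric(tab$cadd_phred)
  tab[need]
}

#' Read a subject x variant genotype presence matrix
#'
#' TSV with subject identifiers in the first column and variant
#' identifiers as the remaining column names; cells are 0/1 presence of
#' at least one alternate allele.
#'
#' @param path TSV file (gzipped accepted).
#' @return integer matrix with subject rownames and variant colnames.
#' @export
readGenotypes <- function(path) {
  tab <- utils::read.table(path,
    header = TRUE, sep = "\t",
    row.names = 1, check.names = FALSE
  )
  as.matrix(tab)
}

#' Extract genotype presence from a VCF
#'
#' Thin convenience reader: converts the genotypes of a VCF into the 0/1
#' subject x variant presence matrix expected by [buildBurden()] (1 =
#' at least one alternate allele). Annotation (gene, consequence, MAF,
#' CADD) is consumed from a separate table, not computed here. Requires
#' the VariantAnnotation package.
#'
#' @param path a VCF file.
#' @param genome genome tag passed to the VCF reader (default "unknown").
#' @return integer matrix, subjects x variants.
#' @export
readVcfGenotypes <- function(path, genome = "unknown") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("readVcfGenotypes requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  gt <- VariantAnnotation::geno(vcf)$GT
  present <- !(gt %in% c("0/0", "0|0", "./.", ".|.", "."))
  dim(present) <- dim(gt)
  out <- t(matrix(as.integer(present), nrow(gt), ncol(gt)))
  dimnames(out) <- list(colnames(gt), rownames(gt))
  out
}

#' Read a phenotype/covariate table
#'
#' TSV with header; the first column holds subject identifiers and a
#' column named `status` holds the 0/1 case-control phenotype. Remaining
#' columns are covariates.
#'
#' @param path TSV file.
#' @return `data.frame` with subject rownames.
#' @export
readPhenotypes <- function(path) {
  tab <- utils::read.table(path,
    header = TRUE, sep = "\t",
    row.names = 1, check.names = FALSE
  )
  if (!"status" %in% names(tab)) {
    stop("phenotype table must contain a 'status' column")
  }
  tab
}

#' Read gene sets in GMT format
#'
#' @param path a GMT file (one set per line: name, description, genes).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a network as a three-column edge list
#'
#' Upper-triangle edges (geneA < geneB lexicographically within each pair)
#' with their weights; a binarized adjacency is written with weight 1. A
#' `.gz` suffix compresses transparently.
#'
#' @param net a [GeneNetwork].
#' @param path output file.
#' @export
writeNetwork <- function(net, path) {
  stopifnot(is(net, "GeneNetwork"))
  ed <- edgeTable(net)
  out <- data.frame(
    geneA = net@genes[ed$i], geneB = net@genes[ed$j], weight = ed$w
  )
  out <- out[order(out$geneA, out$geneB), ]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# shared writer for subject x gene matrices
writeSubjectGeneTsv <- function(m, subjectIds, geneIds, path) {
  tab <- data.frame(subject = subjectIds, as.matrix(m),
    check.names = FALSE)
  names(tab) <- c("subject", geneIds)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a burden or score matrix as TSV (subjects x genes)
#'
#' For [SmoothedScores], a JSON sidecar (`<path>.json`) records run
#' metadata: alpha, tolerance, iterations, convergence and a hash of the
#' gene order, so downstream runs can verify alignment.
#'
#' @param x a [BurdenMatrix] or [SmoothedScores].
#' @param path output TSV (a `.gz` suffix compresses).
#' @export
writeScores <- function(x, path) {
  if (is(x, "BurdenMatrix")) {
    return(writeSubjectGeneTsv(x@values, x@subjects, x@genes, path))
  }
  stopifnot(is(x, "SmoothedScores"))
  writeSubjectGeneTsv(x@values, x@subjects, x@genes, path)
  meta <- list(
    alpha = x@alpha, tol = x@tol, iterations = x@iterations,
    finalDelta = x@finalDelta, converged = x@converged,
    nSubjects = length(x@subjects), nGenes = length(x@genes),
    geneOrderHash = sum(utf8ToInt(paste(x@genes, collapse = "|")))
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a subject x gene matrix written by [writeScores()]
#'
#' @param path TSV file.
#' @return numeric matrix, subjects in rows.
#' @export
readScores <- function(path) {
  tab <- utils::read.table(path,
    header = TRUE, sep = "\t",
    row.names = 1, check.names = FALSE
  )
  as.matrix(tab)
}
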