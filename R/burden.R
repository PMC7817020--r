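#' Filter annotated rare variants
#'
#' Applies the rare-deleterious inclusion rule to a pre-annotated variant
#' table: a variant is kept when its population minor allele frequency is
#' strictly below `mafMax`, its consequence class is in `consequences`, and
#' its CADD phred score is strictly above `caddMin`. Frameshift variants
#' commonly lack CADD scores; with `frameshiftCaddExempt = TRUE` they pass
#' the deleteriousness filter regardless (the convention used when the
#' burden is restricted to stop-gain, stop-loss and frameshift variants,
#' where the CADD cutoff applies to the stop variants only).
#'
#' Records with a missing required annotation (gene, MAF, consequence, or
#' CADD where the CADD rule applies) are excluded with a warning giving the
#' total count.
#'
#' @param variants `data.frame` with columns `variant_id`, `gene`,
#'   `consequence`, `maf`, `cadd_phred` (see [readVariants()]).
#' @param mafMax MAF cutoff in (0, 1); default 0.01 (rare = MAF < 1%).
#' @param caddMin CADD phred cutoff; default 20 (approximately the top 1%
#'   most deleterious substitutions).
#' @param consequences consequence classes to keep.
#' @param frameshiftCaddExempt let frameshift variants bypass the CADD rule.
#' @return the filtered `data.frame`, input order preserved.
#' @export
filterVariants <- function(variants,
                           mafMax = 0.01,
                           caddMin = 20,
                           consequences = c(
                             "missense", "stop-gain",
                             "stop-loss", "frameshift"
                           ),
                           frameshiftCaddExempt = FALSE) {
  stopifnot(is.data.frame(variants))
  need <- c("variant_id", "gene", "consequence", "maf", "cadd_phred")
  miss <- setdiff(need, names(variants))
  if (length(miss)) {
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(mafMax) || mafMax <= 0 || mafMax >= 1) {
    stop("mafMax must lie in (0, 1)")
  }
  if (caddMin < 0) stop("caddMin must be >= 0")

  fsExempt <- frameshiftCaddExempt & variants$consequence == "frameshift"
  caddNeeded <- !fsExempt
  incomplete <- is.na(variants$gene) | variants$gene == "" |
    is.na(variants$maf) | is.na(variants$consequence) |
    (caddNeeded & is.na(variants$cadd_phred))
  if (any(incomplete)) {
    warning(sprintf(
      "excluded %d record(s) with missing required annotations",
      sum(incomplete)
    ))
  }
  cadd <- variants$cadd_phred
  keep <- !incomplete &
    variants$maf < mafMax &
    variants$consequence %in% consequences &
    (fsExempt | (!is.na(cadd) & cadd > caddMin))
  variants[keep, , drop = FALSE]
}

#' Build the subject x gene burden matrix
#'
#' Maps filtered variants to their genes and aggregates the subject x
#' variant genotype presence matrix into the subject x gene matrix G0:
#' with `encoding = "status"` a cell is 1 iff the subject carries at least
#' one qualifying variant in the gene; with `encoding = "burden"` it is the
#' count of such variants. When a companion network is supplied, genes
#' absent from it are dropped (with a message giving the count) and network
#' genes with no qualifying variants appear as all-zero columns, so the
#' burden columns align exactly with the network's gene order.
#'
#' @param variants filtered variant table (see [filterVariants()]).
#' @param genotypes subject x variant matrix of 0/1 presence (>= 1
#'   alternate allele), with subject rownames and variant_id colnames.
#' @param encoding `"status"` (default) or `"burden"`.
#' @param network optional [GeneNetwork] whose gene order the burden must
#'   follow.
#' @return a [BurdenMatrix].
#' @export
buildBurden <- function(variants, genotypes,
                        encoding = c("status", "burden"),
                        network = NULL) {
  encoding <- match.arg(encoding)
  stopifnot(is.data.frame(variants))
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes))) {
    stop("genotypes must carry subject rownames and variant_id colnames")
  }
  missing <- setdiff(variants$variant_id, colnames(genotypes))
  if (length(missing)) {
    stop(
      "variant id(s) absent from the genotype matrix: ",
      paste(utils::head(missing, 10), collapse = ", ")
    )
  }
  vid <- as.character(variants$variant_id)
  vgene <- as.character(variants$gene)
  if (is.null(network)) {
    geneOrder <- sort(unique(vgene))
  } else {
    geneOrder <- network@genes
    outside <- !vgene %in% geneOrder
    if (any(outside)) {
      message(sprintf(
        "dropped %d variant(s) in %d gene(s) absent from the network",
        sum(outside), length(unique(vgene[outside]))
      ))
      vid <- vid[!outside]
      vgene <- vgene[!outside]
    }
  }
  g <- asSparse(genotypes[, vid, drop = FALSE] != 0)
  # variant -> gene indicator (variants x genes), counts via one product
  map <- Matrix::sparseMatrix(
    i = seq_along(vid), j = match(vgene, geneOrder),
    x = 1, dims = c(length(vid), length(geneOrder))
  )
  counts <- asSparse(g %*% map)
  vals <- if (encoding == "status") asSparse(counts != 0) else counts
  dimnames(vals) <- list(rownames(genotypes), geneOrder)
  new("BurdenMatrix",
    subjects = rownames(genotypes), genes = geneOrder,
    values = vals, encoding = encoding
  )
}

# Per-gene carrier x case 2x2 tables and odds-ratio directions.
# Returns data.frame(gene, carrierCase, carrierControl, nonCarrierCase,
# nonCarrierControl, oddsRatio, direction).
orientationTable <- function(values, genes, case) {
  carrier <- abs(values) > 0
  cc <- as.numeric(Matrix::colSums(carrier[case, , drop = FALSE]))
  cn <- as.numeric(Matrix::colSums(carrier[!case, , drop = FALSE]))
  nCase <- sum(case)
  nCtrl <- sum(!case)
  a <- cc; b <- cn; c_ <- nCase - cc; d <- nCtrl - cn
  # Haldane-Anscombe continuity correction for direction calling only
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  or <- ((a + 0.5 * zero) * (d + 0.5 * zero)) /
    ((b + 0.5 * zero) * (c_ + 0.5 * zero))
  direction <- ifelse(or > 1, "risk", ifelse(or < 1, "protective",
    "undetermined"))
  allOrNone <- (cc + cn) == 0 | (cc + cn) == nCase + nCtrl
  direction[allOrNone] <- "undetermined"
  data.frame(
    gene = genes,
    carrierCase = a, carrierControl = b,
    nonCarrierCase = c_, nonCarrierControl = d,
    oddsRatio = or, direction = direction,
    stringsAsFactors = FALSE
  )
}

#' Orient gene effects by phenotype
#'
#' Network propagation is sensitive to the direction of a gene's effect:
#' signal flowing into a hub from a protective gene must be numerically
#' distinguishable from signal arriving from a risk gene. For every gene,
#' the 2x2 carrier/non-carrier x case/control table is built over the
#' phenotyped subjects and the odds ratio determines the direction (OR > 1
#' risk, OR < 1 protective; zero cells receive the Haldane-Anscombe 0.5
#' correction for direction calling only, and an OR of exactly 1 or an
#' all-/no-carrier gene leaves the direction undetermined and the column
#' unchanged). The `mode` then rewrites the matrix:
#' * `"signed"` — risk columns become +|value|, protective columns
#'   -|value| (so a 0/1 status matrix becomes -1/0/+1);
#' * `"zero_protective"` / `"zero_risk"` — the respective columns are set
#'   to zero;
#' * `"none"` — identity; only the metadata is attached.
#'
#' Orientation uses phenotyped subjects only, but the rewritten columns
#' apply to all subjects in the matrix (the typical workflow propagates the
#' full cohort while orientation and selection use the case/control
#' subset).
#'
#' @param burden a [BurdenMatrix] with `status` encoding (a previously
#'   signed matrix is accepted; carrier status is taken as `|value| > 0`,
#'   which makes the operation idempotent).
#' @param phenotype named 0/1 vector (or two-level factor, second level =
#'   case) for at least the subjects used to orient; no missing values
#'   among those subjects.
#' @param mode orientation mode, see above.
#' @return a [BurdenMatrix] with orientation metadata in
#'   [orientation()] and encoding `"signed_status"` under `"signed"`.
#' @export
orientEffects <- function(burden, phenotype,
                          mode = c("signed", "zero_protective",
                                   "zero_risk", "none")) {
  mode <- match.arg(mode)
  stopifnot(is(burden, "BurdenMatrix"))
  if (!burden@encoding %in% c("status", "signed_status")) {
    stop("effect orientation requires a status-encoded burden")
  }
  y <- asPhenotype(phenotype)
  if (is.null(names(y))) {
    if (length(y) != length(burden@subjects)) {
      stop("unnamed phenotype must cover every subject in order")
    }
    names(y) <- burden@subjects
  }
  use <- intersect(burden@subjects, names(y)[!is.na(y)])
  if (length(use) < 2 || length(unique(y[use])) < 2) {
    stop("phenotype must contain both cases and controls")
  }
  sub <- match(use, burden@subjects)
  ortab <- orientationTable(
    burden@values[sub, , drop = FALSE], burden@genes,
    case = y[use] == 1L
  )
  vals <- burden@values
  if (mode != "none") {
    prot <- which(ortab$direction == "protective")
    risk <- which(ortab$direction == "risk")
    if (mode == "signed") {
      vals <- abs(vals)
      if (length(prot)) vals[, prot] <- -vals[, prot, drop = FALSE]
    } else if (mode == "zero_protective" && length(prot)) {
      vals[, prot] <- 0
    } else if (mode == "zero_risk" && length(risk)) {
      vals[, risk] <- 0
    }
  }
  vals <- asSparse(vals)
  dimnames(vals) <- list(burden@subjects, burden@genes)
  enc <- if (mode == "signed") "signed_status" else burden@encoding
  new("BurdenMatrix",
    subjects = burden@subjects, genes = burden@genes,
    values = vals, encoding = enc, orientation = ortab
  )
}
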