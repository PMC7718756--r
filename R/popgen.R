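# Population-genetic utilities: SNP quality control, pairwise LD, and
# candidate-gene window queries around significant loci.

#' Quality-filter a dosage genotype matrix
#'
#' PLINK-style filtering applied in a fixed order, with counts reported per
#' step: (1) drop individuals with genotype call rate below
#' `ind_callrate_min`; (2) drop SNPs with minor allele frequency below
#' `maf_min` (a SNP exactly at the threshold is retained); (3) drop SNPs
#' whose genotype frequencies fail a 1-df chi-square Hardy-Weinberg test at
#' `hwe_p_min` (no continuity correction).
#'
#' @param genos individuals x SNPs matrix of dosages `0/1/2` (`NA`
#'   missing).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param ind_callrate_min minimum individual call rate (default 0.90).
#' @param hwe_p_min minimum Hardy-Weinberg p-value (default 0.001).
#' @return list with `genotypes` (the filtered matrix) and `report`, a data
#'   frame of removal counts per filter in application order.
#' @export
snp_qc_filter <- function(genos, maf_min = 0.05, ind_callrate_min = 0.90,
                          hwe_p_min = 0.001) {
  genos <- as.matrix(genos)
  if (!all(genos %in% c(0, 1, 2, NA)))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  callrate <- rowMeans(!is.na(genos))
  drop_ind <- callrate < ind_callrate_min
  g1 <- genos[!drop_ind, , drop = FALSE]

  maf <- apply(g1, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(0)
    p <- mean(x) / 2
    min(p, 1 - p)
  })
  drop_maf <- maf < maf_min
  g2 <- g1[, !drop_maf, drop = FALSE]

  hwe_p <- apply(g2, 2, hwe_pvalue)
  drop_hwe <- hwe_p < hwe_p_min
  g3 <- g2[, !drop_hwe, drop = FALSE]

  if (!nrow(g3) || !ncol(g3))
    stop("all individuals or SNPs removed by quality filtering",
         call. = FALSE)
  report <- data.frame(
    filter = c("individual_callrate", "maf", "hwe"),
    removed = c(sum(drop_ind), sum(drop_maf), sum(drop_hwe)),
    remaining_ind = c(nrow(g1), nrow(g2), nrow(g3)),
    remaining_snp = c(ncol(g1), ncol(g2), ncol(g3)))
  list(genotypes = g3, report = report)
}

#' Hardy-Weinberg chi-square p-value for one SNP
#'
#' 1-df goodness-of-fit chi-square of the observed genotype counts against
#' Hardy-Weinberg expectations, without continuity correction. Monomorphic
#' SNPs return p = 1 (no departure is testable).
#'
#' @param dosages vector of `0/1/2` dosages (`NA` dropped).
#' @return the p-value.
#' @export
hwe_pvalue <- function(dosages) {
  x <- dosages[!is.na(dosages)]
  n <- length(x)
  if (!n) return(1)
  obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Pairwise LD as squared dosage correlation
#'
#' `r^2` between two SNPs: the squared Pearson correlation of their allele
#' dosages over individuals non-missing at both. Invariant to allele
#' flipping.
#'
#' @param snp1,snp2 dosage vectors (`0/1/2`, `NA` missing).
#' @return `r^2` in `[0, 1]`, or `NA` with a warning when either SNP has no
#'   variance among the shared individuals.
#' @export
pairwise_ld_r2 <- function(snp1, snp2) {
  ok <- !is.na(snp1) & !is.na(snp2)
  if (sum(ok) < 2)
    stop("need at least 2 shared non-missing individuals", call. = FALSE)
  x <- snp1[ok]; y <- snp2[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance SNP: LD undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Gene annotation table
#'
#' @param gene_id,chromosome,start_bp,stop_bp,product per-gene fields;
#'   coordinates 1-based inclusive (GFF3 convention).
#' @return data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chromosome, start_bp, stop_bp,
                            product = NA_character_) {
  product <- rep_len(as.character(product), length(gene_id))
  df <- data.frame(gene_id = as.character(gene_id),
                   chromosome = as.character(chromosome),
                   start_bp = as.numeric(start_bp),
                   stop_bp = as.numeric(stop_bp),
                   product = as.character(product))
  if (any(df$start_bp > df$stop_bp))
    stop("gene start must not exceed stop", call. = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a gene annotation (GFF3 or CSV)
#'
#' GFF3 files (`.gff`, `.gff3`) are parsed with \pkg{rtracklayer}; `gene`
#' features are kept and the `ID` and `product` (or `description`)
#' attributes extracted. CSV files need columns
#' `gene_id, chromosome, start_bp, stop_bp` and optionally `product`.
#'
#' @param path annotation file.
#' @return a [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    prod <- if ("product" %in% names(S4Vectors::mcols(gr))) gr$product
            else if ("description" %in% names(S4Vectors::mcols(gr)))
              gr$description
            else NA_character_
    gene_annotation(gr$ID, as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr), GenomicRanges::end(gr),
                    as.character(prod))
  } else {
    df <- utils::read.csv(path, comment.char = "#")
    gene_annotation(df$gene_id, df$chromosome, df$start_bp, df$stop_bp,
                    if ("product" %in% names(df)) df$product else NA)
  }
}

#' Candidate genes within a window of significant SNPs
#'
#' For each SNP, reports every annotated gene whose 1-based inclusive span
#' intersects the closed window `[snp - window_bp, snp + window_bp]`, sorted
#' by distance from the SNP (0 when the SNP lies inside the gene). SNPs on
#' chromosomes absent from the annotation are skipped with a warning.
#'
#' @param snps data frame with columns `chromosome, bp` (one row per
#'   significant SNP).
#' @param annotation a [gene_annotation()].
#' @param window_bp half-width of the scan window (default 100 kb).
#' @return data frame `chromosome, snp_bp, gene_id, start_bp, stop_bp,
#'   product, distance_bp`.
#' @export
candidate_gene_window <- function(snps, annotation, window_bp = 100000) {
  stopifnot(is.data.frame(snps), all(c("chromosome", "bp") %in% names(snps)))
  unknown <- setdiff(unique(snps$chromosome), unique(annotation$chromosome))
  if (length(unknown) && nrow(annotation))
    warning("SNP chromosome(s) absent from annotation, skipped: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    chr <- snps$chromosome[i]; pos <- snps$bp[i]
    ann <- annotation[annotation$chromosome == chr, , drop = FALSE]
    hit <- ann[ann$start_bp <= pos + window_bp &
               ann$stop_bp >= pos - window_bp, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    dist <- ifelse(pos >= hit$start_bp & pos <= hit$stop_bp, 0,
                   pmin(abs(pos - hit$start_bp), abs(pos - hit$stop_bp)))
    out <- data.frame(chromosome = chr, snp_bp = pos,
                      gene_id = hit$gene_id, start_bp = hit$start_bp,
                      stop_bp = hit$stop_bp, product = hit$product,
                      distance_bp = dist)
    out[order(out$distance_bp), , drop = FALSE]
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(chromosome = character(), snp_bp = numeric(),
                      gene_id = character(), start_bp = numeric(),
                      stop_bp = numeric(), product = character(),
                      distance_bp = numeric())
  rownames(res) <- NULL
  res
}
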