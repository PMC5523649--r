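# Cohort file I/O: VCF 4.2 genotypes (GT only, biallelic SNVs) with TSV
# sidecars for variant annotations, subjects, phenotypes and readouts.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE, ...)
}

#' Write a cohort dataset to a directory
#'
#' Emits \code{genotypes.vcf} (VCF 4.2, GT field only, \code{./.} for
#' missing), \code{variants.tsv} (annotation sidecar), \code{subjects.tsv},
#' \code{phenotypes.tsv}, \code{readouts.tsv} and, when the cohort carries
#' simulation truth, \code{truth.json}. Round-trips losslessly through
#' [read_cohort()].
#'
#' @param cohort a \code{cohort} object (see [simulate_cohort()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!nrow(cohort$subjects)) stop("cannot write an empty cohort (0 subjects)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- cohort$genotypes
  files <- c(
    genotypes = file.path(dir, "genotypes.vcf"),
    variants = file.path(dir, "variants.tsv"),
    subjects = file.path(dir, "subjects.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    readouts = file.path(dir, "readouts.tsv"))
  write_vcf(g, files["genotypes"])
  .write_tsv(g$variants[, c("id", "gene", "region_class", "functional_flag")],
             files["variants"])
  .write_tsv(cohort$subjects, files["subjects"])
  .write_tsv(cohort$phenotypes, files["phenotypes"])
  if (!is.null(cohort$readouts)) .write_tsv(cohort$readouts, files["readouts"])
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    truth <- list(
      hap1 = apply(tr$hap1, 1, paste, collapse = ""),
      hap2 = apply(tr$hap2, 1, paste, collapse = ""),
      latent = tr$latent,
      planted_pqtl = tr$planted_pqtl)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, truth = file.path(dir, "truth.json"))
  }
  invisible(files)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' GT-only, unphased, biallelic SNVs; missing calls become \code{./.}.
#'
#' @param g a \code{geno_matrix}.
#' @param path output file.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  v <- g$variants
  gt_map <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    cc <- g$codes[, j]
    gt <- ifelse(is.na(cc), "./.", gt_map[cc + 1L])
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=protqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$subject_ids), collapse = "\t"),
    body), path)
  invisible(path)
}

#' Read genotypes from a VCF with an annotation sidecar
#'
#' Reads GT fields through \pkg{vcfR}, codes genotypes additively (count of
#' alternate alleles, \code{NA} for missing), skips multi-allelic and
#' non-SNV records with a logged count, and joins the annotation TSV by
#' variant id. Unannotated variants default to
#' \code{region_class = "intergenic"}, \code{functional_flag = FALSE}.
#'
#' @param vcf_path VCF file (GT format field required).
#' @param annotation_tsv_path optional TSV with columns \code{id},
#'   \code{gene}, \code{region_class}, \code{functional_flag}.
#' @return a \code{geno_matrix}.
#' @export
read_genotypes <- function(vcf_path, annotation_tsv_path = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$REF != fix$ALT &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!keep))
    message(sum(!keep), " multi-allelic/non-SNV record(s) skipped")
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                fix$ID)
  code1 <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(strsplit(s, "[/|]")[[1]] == "1")
  }
  codes <- t(apply(gt, c(1, 2), code1))
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  if (!is.null(annotation_tsv_path)) {
    ann <- .read_tsv(annotation_tsv_path)
    idx <- match(variants$id, ann$id)
    variants$gene <- ann$gene[idx]
    variants$region_class <- ifelse(is.na(idx), "intergenic",
                                    ann$region_class[idx])
    variants$functional_flag <- ifelse(is.na(idx), FALSE,
                                       ann$functional_flag[idx])
  }
  genotype_matrix(codes, variants, colnames(gt))
}

#' Read a cohort dataset written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return a \code{cohort} object (with \code{truth} when
#'   \code{truth.json} is present).
#' @export
read_cohort <- function(dir) {
  g <- read_genotypes(file.path(dir, "genotypes.vcf"),
                      file.path(dir, "variants.tsv"))
  subjects <- .read_tsv(file.path(dir, "subjects.tsv"),
                        colClasses = c(id = "character"))
  phenotypes <- .read_tsv(file.path(dir, "phenotypes.tsv"),
                          colClasses = c(subject_id = "character"))
  readouts_path <- file.path(dir, "readouts.tsv")
  readouts <- if (file.exists(readouts_path))
    .read_tsv(readouts_path, colClasses = c(subject_id = "character")) else NULL
  truth <- NULL
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    split_haps <- function(v) {
      m <- t(vapply(strsplit(v, ""), as.integer,
                    integer(nchar(v[1]))))
      dimnames(m) <- list(subjects$id, g$variants$id)
      m
    }
    truth <- list(hap1 = split_haps(tj$hap1), hap2 = split_haps(tj$hap2),
                  latent = tj$latent, planted_pqtl = tj$planted_pqtl)
  }
  structure(list(subjects = subjects, genotypes = g,
                 phenotypes = phenotypes, readouts = readouts,
                 truth = truth), class = "cohort")
}
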