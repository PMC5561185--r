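# Genotype and phenotype file I/O.

#' Construct a genotype matrix object
#'
#' @param sample_ids ordered sample identifiers.
#' @param snps data.frame of per-variant metadata (`snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `imputation_r2`, `call_rate`).
#' @param dosages samples x variants matrix of effect-allele dosages in
#'   `[0, 2]`, NA for missing.
#' @return object of class `genotype_matrix`.
#' @export
new_genotype_matrix <- function(sample_ids, snps, dosages) {
  dosages <- as.matrix(dosages)
  stopifnot(
    nrow(dosages) == length(sample_ids),
    ncol(dosages) == nrow(snps),
    all(snps$effect_allele != snps$other_allele)
  )
  rng <- if (anyNA(dosages)) range(dosages, na.rm = TRUE) else range(dosages)
  if (nrow(dosages) > 0 && is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snps$snp_id
  structure(list(sample_ids = sample_ids, snps = snps, dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d variants (%.2f%% missing)\n",
              length(x$sample_ids), nrow(x$snps),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Read a VCF file into a genotype matrix
#'
#' Dosages come from the `DS` FORMAT field when present, else from allele
#' counts of `GT`; they are oriented to the ALT allele (the effect allele).
#' Missing genotypes are preserved as NA. Per-variant imputation quality is
#' taken from an `R2` (or `DR2`) INFO key when present; absent means directly
#' genotyped.
#'
#' @param path path to an uncompressed VCF v4.2 file.
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  # light structural pre-check so malformed lines are reported by number
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  if (length(body) == 0L) stop("VCF contains no variant records: ", path, call. = FALSE)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1L) stop("VCF is missing its #CHROM header line", call. = FALSE)
  n_expected <- length(strsplit(hdr, "\t", fixed = TRUE)[[1]])
  bad <- body[nf != n_expected]
  if (length(bad) > 0L) {
    stop("malformed VCF record at line ", bad[1], " (", nf[body == bad[1]][1],
         " fields, expected ", n_expected, ")", call. = FALSE)
  }

  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- rbind(vcfR::getFIX(v, getINFO = TRUE))  # rbind keeps 1-row files a matrix
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic site(s) not supported: ",
         paste(fix[multi, "ID"], collapse = ", "), call. = FALSE)
  }
  info <- fix[, "INFO"]
  r2 <- suppressWarnings(as.numeric(sub(".*\\b(?:D?R2)=([^;]+).*", "\\1",
                                        info, perl = TRUE)))
  r2[!grepl("\\bD?R2=", info, perl = TRUE)] <- NA_real_

  gt_present <- "GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID ||
    any(grepl("GT", v@gt[, 1]))
  ds <- if (any(grepl("DS", v@gt[, 1]))) {
    suppressWarnings(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
  } else NULL
  gtm <- if (gt_present) vcfR::extract.gt(v, element = "GT") else NULL

  gt_dosage <- function(g) {
    # count ALT alleles; any missing allele makes the genotype missing
    out <- rep(NA_real_, length(g))
    known <- !is.na(g) & !grepl("\\.", g)
    out[known] <- vapply(strsplit(g[known], "[/|]"),
                         function(a) sum(a == "1"), numeric(1))
    out
  }
  if (!is.null(ds)) {
    dos <- ds
    if (!is.null(gtm) && anyNA(ds)) {
      fill <- is.na(ds) & !is.na(gtm)
      if (any(fill)) dos[fill] <- gt_dosage(gtm[fill])
    }
  } else if (!is.null(gtm)) {
    dos <- apply(gtm, 2, gt_dosage)
    dim(dos) <- dim(gtm)
    dimnames(dos) <- dimnames(gtm)
  } else {
    stop("VCF has neither DS nor GT FORMAT fields", call. = FALSE)
  }

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  dos <- t(dos)  # samples x variants
  snps <- data.frame(
    snp_id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    effect_allele = alt, other_allele = fix[, "REF"],
    imputation_r2 = r2,
    call_rate = colMeans(!is.na(dos)),
    stringsAsFactors = FALSE
  )
  new_genotype_matrix(rownames(dos), snps, dos)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a `DS` FORMAT field always and a `GT` field when all non-missing
#' dosages are hard genotypes (0/1/2); imputation quality goes into an
#' `R2` INFO key.
#'
#' @param gm a `genotype_matrix`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  dos <- gm$dosages
  hard <- all(is.na(dos) | dos %in% c(0, 1, 2))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path, call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    if (hard) "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  ), con)
  fmt <- if (hard) "GT:DS" else "DS"
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(gm$snps))) {
    s <- gm$snps[j, ]
    d <- dos[, j]
    ds_str <- ifelse(is.na(d), ".", formatC(d, format = "g", digits = 6))
    cells <- if (hard) {
      gt <- ifelse(is.na(d), "./.", gt_codes[d + 1])
      paste(gt, ds_str, sep = ":")
    } else ds_str
    info <- if (is.na(s$imputation_r2)) "." else sprintf("R2=%g", s$imputation_r2)
    writeLines(paste(c(s$chrom, s$pos, s$snp_id, s$other_allele, s$effect_allele,
                       ".", "PASS", info, fmt, cells), collapse = "\t"), con)
  }
  invisible(path)
}

phenotype_columns <- c("sample_id", "hair_color", "cortisol_pgmg",
                       "cortisone_pgmg", "sex", "age_months", "cs_use",
                       "origin_group")

#' Read a cohort phenotype table
#'
#' Expects a TSV with columns `sample_id`, `hair_color`, `cortisol_pgmg`,
#' `cortisone_pgmg`, `sex`, `age_months`, `cs_use`, `origin_group` (matched by
#' header name, any order). Validates ranges: hair colour integer 1-7 or NA,
#' hormones strictly positive (Box-Cox requires positivity), sex/cs_use
#' binary, age positive.
#'
#' @param path path to the TSV file.
#' @return data.frame in canonical column order.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  unknown <- setdiff(names(df), phenotype_columns)
  if (length(unknown) > 0) {
    stop("unknown phenotype column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(phenotype_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("missing phenotype column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[phenotype_columns]
  hc <- df$hair_color
  if (any(!is.na(hc) & (hc != round(hc) | hc < 1 | hc > 7))) {
    stop("hair_color must be an integer in 1..7 (or NA)", call. = FALSE)
  }
  df$hair_color <- as.integer(hc)
  for (h in c("cortisol_pgmg", "cortisone_pgmg")) {
    if (any(!is.na(df[[h]]) & df[[h]] <= 0)) {
      stop(h, " must be strictly positive (Box-Cox transform)", call. = FALSE)
    }
  }
  for (b in c("sex", "cs_use")) {
    if (any(!is.na(df[[b]]) & !df[[b]] %in% c(0, 1))) {
      stop(b, " must be binary 0/1", call. = FALSE)
    }
  }
  if (any(!is.na(df$age_months) & df$age_months <= 0)) {
    stop("age_months must be positive", call. = FALSE)
  }
  df
}

#' Subset a genotype matrix by samples or variants
#'
#' @param gm a `genotype_matrix`.
#' @param sample_ids,snp_ids identifiers to keep (order preserved as given).
#' @return a `genotype_matrix`.
#' @export
subset_samples <- function(gm, sample_ids) {
  idx <- match(sample_ids, gm$sample_ids)
  if (anyNA(idx)) {
    stop("unknown sample id(s): ",
         paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  gm_unchecked(gm$sample_ids[idx], gm$snps, gm$dosages[idx, , drop = FALSE])
}

#' @rdname subset_samples
#' @export
subset_snps <- function(gm, snp_ids) {
  idx <- match(snp_ids, gm$snps$snp_id)
  if (anyNA(idx)) {
    stop("unknown SNP id(s): ",
         paste(utils::head(snp_ids[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  s <- gm$snps[idx, , drop = FALSE]
  rownames(s) <- NULL
  gm_unchecked(gm$sample_ids, s, gm$dosages[, idx, drop = FALSE])
}

# construction without re-validation, for subsetting an already-valid object
gm_unchecked <- function(sample_ids, snps, dosages) {
  structure(list(sample_ids = sample_ids, snps = snps, dosages = dosages),
            class = "genotype_matrix")
}
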