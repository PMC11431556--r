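#' GWAS summary statistics for one trait
#'
#' Construct a validated container of per-SNP association summaries for a
#' single trait. Each record carries the variant identifier, genomic
#' coordinates (1-based), the effect and other alleles, the effect-allele
#' frequency, the per-allele effect estimate with its standard error and
#' p-value, and the analysed sample size. For binary traits the effect is
#' interpreted on the log-odds scale; for continuous traits in SD units.
#'
#' Rows violating the record invariants (non-ACGT or identical alleles,
#' non-positive standard error, allele frequency outside (0,1), p-value
#' outside (0,1], non-positive sample size, non-finite effect) are dropped
#' with a message rather than failing the whole table: summary statistics in
#' the wild are messy. Rows whose p-value disagrees with the normal-theory
#' value 2*pnorm(-|beta/se|) by more than a factor of two are flagged (not
#' dropped) -- files may carry exact p-values from other tests.
#'
#' @param records data.frame with columns SNP, CHR, BP, EA, OA, EAF, BETA,
#'   SE, P, N (the canonical schema).
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param quiet suppress the dropped-row message.
#' @return An object of class `gwas_sumstats`: the validated data.frame with
#'   attributes `trait_id`, `trait_type`, `n_dropped`.
#' @export
gwas_sumstats <- function(records, trait_id, trait_type = c("continuous", "binary"),
                          quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records), is.character(trait_id), length(trait_id) == 1L)
  req <- .canonical_cols
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[req]
  records$SNP <- as.character(records$SNP)
  records$CHR <- as.character(records$CHR)
  records$EA <- toupper(as.character(records$EA))
  records$OA <- toupper(as.character(records$OA))
  for (cc in c("BP", "EAF", "BETA", "SE", "P", "N")) {
    records[[cc]] <- suppressWarnings(as.numeric(records[[cc]]))
  }

  bases <- c("A", "C", "G", "T")
  ok <- !is.na(records$SNP) & nzchar(records$SNP) &
    records$EA %in% bases & records$OA %in% bases & records$EA != records$OA &
    is.finite(records$BETA) &
    is.finite(records$SE) & records$SE > 0 &
    is.finite(records$EAF) & records$EAF > 0 & records$EAF < 1 &
    is.finite(records$P) & records$P > 0 & records$P <= 1 &
    is.finite(records$N) & records$N > 0
  ok[is.na(ok)] <- FALSE
  n_dropped <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  if (anyDuplicated(records$SNP)) {
    dup <- duplicated(records$SNP)
    n_dropped <- n_dropped + sum(dup)
    records <- records[!dup, , drop = FALSE]
  }
  if (n_dropped > 0L && !quiet) {
    message(sprintf("[%s] dropped %d invalid/duplicate row(s)", trait_id, n_dropped))
  }

  # flag (never drop) p-values inconsistent with the reported beta/se
  if (nrow(records) > 0L) {
    p_theory <- 2 * stats::pnorm(-abs(records$BETA / records$SE))
    inconsistent <- p_theory > 0 & (records$P / p_theory > 2 | p_theory / records$P > 2)
    if (any(inconsistent) && !quiet) {
      message(sprintf("[%s] %d row(s) with p-value inconsistent with beta/se (kept, flagged)",
                      trait_id, sum(inconsistent)))
    }
  }

  rownames(records) <- NULL
  structure(records,
            trait_id = trait_id, trait_type = trait_type, n_dropped = n_dropped,
            class = c("gwas_sumstats", "data.frame"))
}

.canonical_cols <- c("SNP", "CHR", "BP", "EA", "OA", "EAF", "BETA", "SE", "P", "N")

#' @export
print.gwas_sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Default column-name dialect
#'
#' Maps the canonical internal column names to themselves and is the starting
#' point for adapting other headers (GWAS-Catalog-style files, for instance,
#' use `variant_id`, `chromosome`, `base_pair_location`, `effect_allele`,
#' `other_allele`, `effect_allele_frequency`, `beta`, `standard_error`,
#' `p_value`, `n`).
#'
#' @return Named character vector mapping canonical name -> file column name.
#' @export
default_dialect <- function() {
  stats::setNames(.canonical_cols, .canonical_cols)
}

#' GWAS-Catalog-style column dialect
#' @return Named character vector usable as the `dialect` of [read_sumstats()].
#' @export
gwas_catalog_dialect <- function() {
  c(SNP = "variant_id", CHR = "chromosome", BP = "base_pair_location",
    EA = "effect_allele", OA = "other_allele", EAF = "effect_allele_frequency",
    BETA = "beta", SE = "standard_error", P = "p_value", N = "n")
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Accepts tab- or comma-delimited files with a header row; gzip-compressed
#' input (`.gz`) is read transparently. Columns are mapped to the canonical
#' schema through `dialect` and the resulting table is validated by
#' [gwas_sumstats()] (invalid rows dropped with a logged count).
#'
#' @param path file path.
#' @param trait_id trait identifier; defaults to the file name.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param dialect named character vector mapping canonical column names
#'   (`SNP`, `CHR`, `BP`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N`) to the
#'   file's column names. See [default_dialect()], [gwas_catalog_dialect()].
#' @param quiet suppress messages.
#' @return A [gwas_sumstats()] object.
#' @export
read_sumstats <- function(path, trait_id = basename(path),
                          trait_type = c("continuous", "binary"),
                          dialect = default_dialect(), quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  first <- readLines(con, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- utils::read.table(con, header = FALSE, sep = sep, quote = "\"",
                          col.names = strsplit(first, sep, fixed = TRUE)[[1]],
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", blank.lines.skip = TRUE,
                          fill = TRUE)
  if (nrow(df) == 0L) stop("no data rows in ", path)

  missing_cols <- setdiff(unname(dialect[.canonical_cols]), names(df))
  if (length(missing_cols) > 0L) {
    stop("column(s) not found in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  out <- df[unname(dialect[.canonical_cols])]
  names(out) <- .canonical_cols
  gwas_sumstats(out, trait_id = trait_id, trait_type = trait_type, quiet = quiet)
}

#' Write GWAS summary statistics to a canonical TSV
#'
#' Writes the canonical ten-column schema as tab-separated text with a header
#' row. Numeric fields are written with full (15 significant digit)
#' precision so that `read_sumstats(write_sumstats(x))` reproduces `x`
#' field-for-field.
#'
#' @param stats a [gwas_sumstats()] object.
#' @param path output file path.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "gwas_sumstats"))
  df <- as.data.frame(stats)
  for (cc in c("BP", "EAF", "BETA", "SE", "P", "N")) {
    df[[cc]] <- vapply(df[[cc]], function(v) format(v, digits = 15, scientific = NA),
                       character(1))
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(ok)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(ea, oa) unname(.complement[ea]) == oa

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Restricts both traits to shared SNPs and aligns the outcome effect to the
#' exposure's effect allele. When the outcome's alleles are swapped relative
#' to the exposure, the outcome beta sign is flipped and its effect-allele
#' frequency replaced by 1-EAF. Strand flips (A<->T, C<->G complements) are
#' resolved before comparison. Palindromic SNPs (A/T or C/G pairs), whose
#' strand cannot be resolved from the alleles alone, are handled per
#' `palindrome_policy`: `"drop_ambiguous"` (default) removes those whose
#' exposure EAF lies within `maf_window` of 0.5, `"drop_all"` removes every
#' palindromic SNP, `"keep"` keeps them all (alignment by allele labels).
#' SNPs whose allele sets match neither directly nor by complement are
#' dropped.
#'
#' @param exposure,outcome [gwas_sumstats()] objects sharing at least one SNP.
#' @param palindrome_policy one of `"drop_ambiguous"`, `"drop_all"`, `"keep"`.
#' @param maf_window half-width of the ambiguity window around EAF 0.5 for
#'   `drop_ambiguous` (default 0.08, i.e. EAF in 0.42--0.58 is ambiguous).
#' @param quiet suppress messages.
#' @return An object of class `harmonized_set`: data.frame with columns
#'   `SNP`, `CHR`, `BP`, `EA`, `OA`, `eaf_x`, `beta_x`, `se_x`, `pval_x`,
#'   `beta_y`, `se_y`, `pval_y` and attributes `exposure_id`, `outcome_id`.
#'   Zero shared SNPs yields an empty set with a warning (not an error), so
#'   pipelines can skip the pair.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop_ambiguous", "drop_all", "keep"),
                      maf_window = 0.08, quiet = FALSE) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "gwas_sumstats"), inherits(outcome, "gwas_sumstats"))
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)
  shared <- intersect(ex$SNP, ou$SNP)
  if (length(shared) == 0L) {
    warning("no shared SNPs between ", attr(exposure, "trait_id"), " and ",
            attr(outcome, "trait_id"))
    return(.empty_harmonized(attr(exposure, "trait_id"), attr(outcome, "trait_id")))
  }
  ex <- ex[match(shared, ex$SNP), ]
  ou <- ou[match(shared, ou$SNP), ]

  ea_x <- ex$EA; oa_x <- ex$OA
  ea_y <- ou$EA; oa_y <- ou$OA
  pal <- .is_palindromic(ea_x, oa_x)

  same <- ea_y == ea_x & oa_y == oa_x
  swapped <- ea_y == oa_x & oa_y == ea_x
  # strand flip: compare the complement of the outcome's alleles (palindromic
  # SNPs are excluded from complement matching -- for them the complement is
  # indistinguishable from a swap)
  cea_y <- unname(.complement[ea_y]); coa_y <- unname(.complement[oa_y])
  flip_same <- !pal & !same & !swapped & cea_y == ea_x & coa_y == oa_x
  flip_swap <- !pal & !same & !swapped & cea_y == oa_x & coa_y == ea_x

  aligned <- same | flip_same
  flipped <- swapped | flip_swap
  keep <- aligned | flipped
  if (palindrome_policy == "drop_all") {
    keep <- keep & !pal
  } else if (palindrome_policy == "drop_ambiguous") {
    ambiguous <- pal & abs(ex$EAF - 0.5) < maf_window
    keep <- keep & !ambiguous
  }
  n_removed <- sum(!keep)
  if (n_removed > 0L && !quiet) {
    message(sprintf("harmonize: removed %d SNP(s) (incompatible alleles or ambiguous palindrome)",
                    n_removed))
  }

  beta_y <- ifelse(flipped, -ou$BETA, ou$BETA)
  out <- data.frame(
    SNP = ex$SNP, CHR = ex$CHR, BP = ex$BP, EA = ea_x, OA = oa_x,
    eaf_x = ex$EAF,
    beta_x = ex$BETA, se_x = ex$SE, pval_x = ex$P,
    beta_y = beta_y, se_y = ou$SE, pval_y = ou$P,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            exposure_id = attr(exposure, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            class = c("harmonized_set", "data.frame"))
}

.empty_harmonized <- function(exposure_id, outcome_id) {
  out <- data.frame(SNP = character(), CHR = character(), BP = numeric(),
                    EA = character(), OA = character(), eaf_x = numeric(),
                    beta_x = numeric(), se_x = numeric(), pval_x = numeric(),
                    beta_y = numeric(), se_y = numeric(), pval_y = numeric(),
                    stringsAsFactors = FALSE)
  structure(out, exposure_id = exposure_id, outcome_id = outcome_id,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s, k = %d SNPs\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# subset rows of a harmonized set, preserving class and attributes
.subset_harmonized <- function(h, keep) {
  out <- as.data.frame(h)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, exposure_id = attr(h, "exposure_id"),
            outcome_id = attr(h, "outcome_id"),
            class = c("harmonized_set", "data.frame"))
}
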