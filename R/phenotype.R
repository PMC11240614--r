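#' Correction coefficients for 100 kg endpoint adjustment
#'
#' Sex-specific constants of the standard linear endpoint adjustment that
#' brings age and ultrasonic backfat records taken at slaughter-test weight to
#' a common 100 kg body-weight endpoint. `A` enters the age adjustment, `B`
#' the backfat adjustment; the sire-line (male) and sow-line (female) values
#' differ because growth curves do.
#'
#' @param A_sire,A_sow age-adjustment intercepts (days).
#' @param B_sire,B_sow backfat-adjustment offsets (kg, negative by convention).
#' @return A named list of class `adjustment_constants`.
#' @export
adjustment_constants <- function(A_sire = 50.775, A_sow = 46.415,
                                 B_sire = -7.277, B_sow = -9.440) {
  structure(list(A_sire = A_sire, A_sow = A_sow,
                 B_sire = B_sire, B_sow = B_sow),
            class = "adjustment_constants")
}

.sex_constant <- function(sex, male, female) {
  sx <- tolower(as.character(sex))
  is_male <- sx %in% c("male", "m", "sire", "boar", "1")
  is_female <- sx %in% c("female", "f", "sow", "gilt", "2")
  if (!all(is_male | is_female)) {
    stop("unrecognized sex label(s): ",
         paste(utils::head(unique(sx[!(is_male | is_female)])), collapse = ", "))
  }
  ifelse(is_male, male, female)
}

#' Adjust age to a 100 kg body-weight endpoint
#'
#' `100AGE = AGE + (100 - wt) * (AGE - A) / wt`, with the sex-appropriate
#' intercept `A`. At `wt = 100` the record is returned unchanged; heavier pigs
#' at the same age adjust to a younger 100 kg age.
#'
#' @param age_days age at measurement (days).
#' @param weight body weight at measurement (kg); must be positive.
#' @param sex sex labels (`"male"`/`"female"`, `"M"`/`"F"`, or 1/2), recycled.
#' @param constants an [adjustment_constants()] object.
#' @return Adjusted ages (days).
#' @export
adjust_age_100kg <- function(age_days, weight, sex,
                             constants = adjustment_constants()) {
  if (any(weight <= 0)) stop("weight must be positive")
  if (any(age_days <= 0)) stop("age_days must be positive")
  A <- .sex_constant(sex, constants$A_sire, constants$A_sow)
  age_days + (100 - weight) * (age_days - A) / weight
}

#' Adjust backfat thickness to a 100 kg body-weight endpoint
#'
#' `100BF = BF + (100 - wt) * BF / (wt - B)`, with the sex-appropriate offset
#' `B`. At `wt = 100` the record is returned unchanged; records above 100 kg
#' adjust downward.
#'
#' @param backfat backfat thickness at measurement (mm); non-negative.
#' @param weight body weight at measurement (kg); `weight - B` must be positive.
#' @param sex sex labels as in [adjust_age_100kg()].
#' @param constants an [adjustment_constants()] object.
#' @return Adjusted backfat (mm).
#' @export
adjust_bf_100kg <- function(backfat, weight, sex,
                            constants = adjustment_constants()) {
  if (any(weight <= 0)) stop("weight must be positive")
  if (any(backfat < 0)) stop("backfat must be non-negative")
  B <- .sex_constant(sex, constants$B_sire, constants$B_sow)
  if (any(weight - B <= 0)) stop("weight - B must be positive")
  backfat + (100 - weight) * backfat / (weight - B)
}

#' Adjust a phenotype table to the 100 kg endpoint
#'
#' Convenience wrapper applying [adjust_age_100kg()] and [adjust_bf_100kg()]
#' to a record table.
#'
#' @param pheno data.frame with columns `id`, `sex`, `age`, `bf`, `wt` (and
#'   optionally `sire`, `dam`).
#' @param constants an [adjustment_constants()] object.
#' @return The input with columns `age100` and `bf100` appended.
#' @export
adjust_records <- function(pheno, constants = adjustment_constants()) {
  need <- c("id", "sex", "age", "bf", "wt")
  miss <- setdiff(need, names(pheno))
  if (length(miss) > 0) stop("phenotype table missing column(s): ",
                             paste(miss, collapse = ", "))
  pheno$age100 <- adjust_age_100kg(pheno$age, pheno$wt, pheno$sex, constants)
  pheno$bf100 <- adjust_bf_100kg(pheno$bf, pheno$wt, pheno$sex, constants)
  pheno
}

#' Mid-parent heterosis
#'
#' `MPH = (F1 - MP) / MP * 100` with mid-parent value `MP = (P1 + P2) / 2`,
#' computed per F1 individual and for the group mean. When `group` is given
#' (e.g. sire family), per-group summaries are returned as well; the
#' group-level MPH is the MPH of the group-mean F1 value, which differs in
#' general from the mean of individual MPHs (both are reported, labelled
#' distinctly).
#'
#' @param f1_values numeric vector of F1 phenotypes.
#' @param p1_mean,p2_mean parental trait means (order-symmetric). Scalars, or
#'   vectors of one value per group level when `group` is given.
#' @param group optional grouping factor (one per F1 individual).
#' @param negate if `TRUE`, the sign of all MPH values is flipped — convenience
#'   for lower-is-better traits where a negative raw MPH is favourable.
#' @return An `mph_result`: list with `individual` (data.frame: value, mph,
#'   group) and `groups` (data.frame: group, n, f1_mean, p1, p2, midparent,
#'   mph_of_group_mean, mean_of_individual_mph).
#' @export
mid_parent_heterosis <- function(f1_values, p1_mean, p2_mean, group = NULL,
                                 negate = FALSE) {
  if (is.null(group)) group <- rep("all", length(f1_values))
  group <- as.factor(group)
  lev <- levels(group)
  p1 <- rep_len(p1_mean, length(lev))
  p2 <- rep_len(p2_mean, length(lev))
  mp <- (p1 + p2) / 2
  if (any(mp == 0)) stop("mid-parent value is zero; MPH undefined")
  mp_i <- mp[as.integer(group)]
  sgn <- if (negate) -1 else 1
  mph_i <- sgn * (f1_values - mp_i) / mp_i * 100
  individual <- data.frame(value = f1_values, mph = mph_i, group = group)
  f1_bar <- tapply(f1_values, group, mean)
  groups <- data.frame(
    group = lev,
    n = as.integer(table(group)[lev]),
    f1_mean = as.numeric(f1_bar[lev]),
    p1 = p1, p2 = p2, midparent = mp,
    mph_of_group_mean = sgn * (as.numeric(f1_bar[lev]) - mp) / mp * 100,
    mean_of_individual_mph = as.numeric(tapply(mph_i, group, mean)[lev])
  )
  structure(list(individual = individual, groups = groups), class = "mph_result")
}

#' @export
print.mph_result <- function(x, digits = 3, ...) {
  cat("mid-parent heterosis over", nrow(x$groups), "group(s)\n")
  print(format(x$groups, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Read / write tab-separated phenotype tables
#'
#' The on-disk layout is a header line `id sex age bf wt sire dam` followed by
#' one row per animal.
#'
#' @param path file path.
#' @return For `read_phenotypes`, a data.frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_phenotypes
#' @param pheno a phenotype data.frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
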