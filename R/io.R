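#' NONMEM-style event datasets
#'
#' The event dataset is a data frame with one row per dose or observation,
#' NONMEM-style:
#'
#' * `ID` subject identifier
#' * `TIME` hours since the subject's first dose (nonnegative,
#'   nondecreasing within subject)
#' * `EVID` 1 for dose rows, 0 for observation rows
#' * `AMT` dose amount in mg (dose rows; `NA` on observations)
#' * `DV` observed concentration in mg/L (observation rows; `NA` on doses)
#' * `DVID` analyte flag on observation rows: 1 = parent (VCZ),
#'   2 = metabolite (VNO)
#' * `BLQ` optional: 1 when `DV` is below the assay lower limit of
#'   quantification (0.0005 mg/L); such rows are kept in files but excluded
#'   from fitting
#'
#' Any further columns (sex, age, WT, height, BSA, laboratory values,
#' CYP2C19 phenotype `PHEN`, comedication flags) are carried as subject
#' covariates.
#'
#' @param df a data frame with at least the mandatory columns above.
#' @return A validated `pk_dataset`.
#' @export
pk_dataset <- function(df) {
  need <- c("ID", "TIME", "EVID", "AMT", "DV", "DVID")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(df$TIME < 0)
  if (length(bad))
    stop("negative TIME at row(s) ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  for (id in unique(df$ID)) {
    rows <- which(df$ID == id)
    if (is.unsorted(df$TIME[rows]))
      stop("non-monotone TIME within subject ", id, " (rows ",
           rows[which(diff(df$TIME[rows]) < 0)[1]], "ff)", call. = FALSE)
  }
  dose <- df$EVID == 1
  bad <- which(dose & (is.na(df$AMT) | df$AMT <= 0))
  if (length(bad))
    stop("dose rows need positive AMT; offending row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(dose & !is.na(df$DV))
  if (length(bad))
    stop("dose rows must not carry DV; offending row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  obs <- df$EVID == 0
  bad <- which(obs & !(df$DVID %in% c(1, 2)))
  if (length(bad))
    stop("observation rows need DVID 1 (VCZ) or 2 (VNO); offending row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  structure(df, class = c("pk_dataset", "data.frame"))
}

#' Read / write event datasets
#'
#' Comma-delimited text with a header row; numeric values are written with
#' 17 significant digits so that write-then-read round-trips exactly.
#' Unknown columns are preserved as covariates.
#'
#' @param path file path.
#' @param x a [pk_dataset()].
#' @return `read_dataset` returns a validated [pk_dataset()];
#'   `write_dataset` returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("TIME", "AMT", "DV")) df[[nm]] <- as.numeric(df[[nm]])
  pk_dataset(df)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(x, path) {
  stopifnot(inherits(x, "pk_dataset"))
  out <- as.data.frame(x)
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                          formatC(out[[nm]], digits = 17, format = "g"))
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read / write parameter files
#'
#' Key/value structured text holding the population estimates (one line per
#' fixed effect, the fixed-parameter mask, the IIV values with their
#' convention, and the residual error models). Values round-trip exactly.
#'
#' @param est a list with components `fixed` ([fixed_effects()]), `omega`
#'   ([omega_spec()]) and `sigma` ([sigma_spec()]), as returned by
#'   [vcz_final_estimates()].
#' @param path file path.
#' @return `read_param_file` returns such a list; `write_param_file`
#'   returns `path` invisibly.
#' @export
write_param_file <- function(est, path) {
  num <- function(x) formatC(x, digits = 17, format = "g")
  f <- est$fixed
  lines <- c(
    "schema: voripk-params-1",
    paste("F", num(f$F)), paste("ka", num(f$ka)), paste("V1", num(f$V1)),
    paste("CL1", num(f$CL1)), paste("V2", num(f$V2)),
    paste("Vmax", num(f$Vmax)), paste("Km", num(f$Km)),
    paste("CL2", num(f$CL2)), paste("Imax", num(f$Imax)),
    paste("IC50", num(f$IC50)), paste("theta_NM", num(f$theta_NM)),
    paste("theta_IM", num(f$theta_IM)), paste("theta_PM", num(f$theta_PM)),
    paste("kn", num(f$kn)),
    paste("fixed_mask", paste(f$fixed_mask, collapse = ",")),
    paste("omega_convention", est$omega$convention),
    paste("omega_V1", num(est$omega$raw[["V1"]])),
    paste("omega_CL1", num(est$omega$raw[["CL1"]])),
    paste("omega_CL2", num(est$omega$raw[["CL2"]])),
    paste("omega_Vmax", num(est$omega$raw[["Vmax"]]))
  )
  for (a in c("vcz", "vno")) {
    s <- est$sigma[[a]]
    lines <- c(lines,
               paste0("sigma_", a, "_model ", s$model),
               paste0("sigma_", a, "_prop ", num(s$prop)),
               paste0("sigma_", a, "_add ", num(s$add)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_param_file
#' @export
read_param_file <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^schema: voripk-params-1", lines[1]))
    stop("not a voripk parameter file (missing schema line)", call. = FALSE)
  kv <- strsplit(lines[-1], " ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  g <- function(k) vals[match(k, keys)]
  gn <- function(k) as.numeric(g(k))
  fixed <- fixed_effects(
    F = gn("F"), ka = gn("ka"), V1 = gn("V1"), CL1 = gn("CL1"),
    V2 = gn("V2"), Vmax = gn("Vmax"), Km = gn("Km"), CL2 = gn("CL2"),
    Imax = gn("Imax"), IC50 = gn("IC50"), theta_NM = gn("theta_NM"),
    theta_IM = gn("theta_IM"), theta_PM = gn("theta_PM"), kn = gn("kn"),
    fixed_mask = strsplit(g("fixed_mask"), ",", fixed = TRUE)[[1]]
  )
  omega <- omega_spec(V1 = gn("omega_V1"), CL1 = gn("omega_CL1"),
                      CL2 = gn("omega_CL2"), Vmax = gn("omega_Vmax"),
                      convention = g("omega_convention"))
  sig <- lapply(c(vcz = "vcz", vno = "vno"), function(a) {
    list(model = g(paste0("sigma_", a, "_model")),
         prop = gn(paste0("sigma_", a, "_prop")),
         add = gn(paste0("sigma_", a, "_add")))
  })
  list(fixed = fixed, omega = omega,
       sigma = sigma_spec(vcz = sig$vcz, vno = sig$vno))
}

# assay lower limit of quantification, mg/L (0.5 ng/ml)
VCZ_LLOQ <- 5e-4
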