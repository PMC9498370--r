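# Delimited-text input/output for the fight-network genetics pipeline.
# All files are comma-separated, decimal point, UTF-8, with a header row.

#' Read animal metadata and pen assignments
#'
#' Reads the per-animal metadata table (pen assignment, genetic line, sex,
#' batch and body weight at mixing) used to build pen rosters and the fixed
#' part of the animal model.
#'
#' @param path Path to a CSV file with columns
#'   `animal,pen_id,line,sex,batch,mixing_weight_kg`.
#' @return A `data.frame` with one row per animal. `sex` is restricted to
#'   `"female"`/`"castrate"`; pens must be single-sex and every animal must
#'   appear exactly once.
#' @export
read_animal_metadata <- function(path) {
  df <- read_csv_checked(path, c("animal", "pen_id", "line", "sex", "batch",
                                 "mixing_weight_kg"))
  df$animal <- as.character(df$animal)
  df$pen_id <- as.character(df$pen_id)
  df$line <- as.character(df$line)
  df$sex <- as.character(df$sex)
  df$batch <- as.character(df$batch)
  df$mixing_weight_kg <- as.numeric(df$mixing_weight_kg)
  validate_animal_metadata(df)
  df
}

validate_animal_metadata <- function(df) {
  dup <- df$animal[duplicated(df$animal)]
  if (length(dup) > 0L)
    stop("duplicated animal id(s) in metadata: ", paste(unique(dup), collapse = ", "))
  bad_sex <- setdiff(unique(df$sex), c("female", "castrate"))
  if (length(bad_sex) > 0L)
    stop("unknown sex level(s): ", paste(bad_sex, collapse = ", "),
         " (expected 'female' or 'castrate')")
  mixed <- tapply(df$sex, df$pen_id, function(s) length(unique(s)) > 1L)
  if (any(mixed))
    stop("pen(s) not single-sex: ", paste(names(mixed)[mixed], collapse = ", "))
  if (any(!is.finite(df$mixing_weight_kg)) || any(df$mixing_weight_kg <= 0))
    stop("mixing_weight_kg must be finite and positive")
  invisible(df)
}

#' Extract pen rosters from animal metadata
#'
#' @param animals Data frame from [read_animal_metadata()].
#' @return Named list mapping `pen_id` to the character vector of member
#'   animal ids.
#' @export
pen_rosters <- function(animals) {
  split(animals$animal, animals$pen_id)
}

#' Read dyadic fight records
#'
#' Reads the raw reciprocal-fight table: one row per observed dyadic fight
#' with its total duration in seconds. Multiple rows for the same unordered
#' pair are allowed; durations are summed downstream by
#' [aggregate_fights()]. Every row is validated against the pen rosters so
#' that malformed data fail loudly with the offending row named.
#'
#' @param path CSV with columns `pen_id,animal_a,animal_b,duration_s`.
#' @param rosters Named list of pen rosters (see [pen_rosters()]).
#' @return Validated `data.frame` in file order.
#' @export
read_fight_records <- function(path, rosters) {
  df <- read_csv_checked(path, c("pen_id", "animal_a", "animal_b", "duration_s"))
  df$pen_id <- as.character(df$pen_id)
  df$animal_a <- as.character(df$animal_a)
  df$animal_b <- as.character(df$animal_b)
  df$duration_s <- suppressWarnings(as.numeric(df$duration_s))
  validate_fight_records(df, rosters)
  df
}

validate_fight_records <- function(df, rosters) {
  for (r in seq_len(nrow(df))) {
    pen <- df$pen_id[r]
    a <- df$animal_a[r]; b <- df$animal_b[r]
    d <- df$duration_s[r]
    if (!pen %in% names(rosters))
      stop(sprintf("fight row %d: unknown pen '%s'", r, pen))
    if (is.na(d) || !is.finite(d) || d <= 0)
      stop(sprintf("fight row %d: duration must be a positive number", r))
    if (a == b)
      stop(sprintf("fight row %d: self-pair ('%s' fights itself)", r, a))
    members <- rosters[[pen]]
    for (x in c(a, b)) {
      if (!x %in% members)
        stop(sprintf("fight row %d: animal '%s' is not in the roster of pen '%s'",
                     r, x, pen))
    }
  }
  invisible(df)
}

#' Read performance phenotypes
#'
#' @param path CSV with columns `animal,TDG,LDG,DFI,FE,FBW,HCW,BF,LD`;
#'   missing values are empty fields.
#' @return `data.frame` with numeric trait columns (NA = missing).
#' @export
read_performance <- function(path) {
  cols <- c("animal", perf_trait_names())
  df <- read_csv_checked(path, cols)
  df$animal <- as.character(df$animal)
  for (cn in perf_trait_names()) {
    df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
    inf <- !is.na(df[[cn]]) & !is.finite(df[[cn]])
    if (any(inf))
      stop(sprintf("performance column %s: non-finite value in row %d",
                   cn, which(inf)[1]))
  }
  if (anyDuplicated(df$animal))
    stop("duplicated animal id(s) in performance table")
  df
}

#' Names of the performance traits handled by the pipeline
#' @return Character vector of the eight performance trait columns.
#' @export
perf_trait_names <- function() {
  c("TDG", "LDG", "DFI", "FE", "FBW", "HCW", "BF", "LD")
}

#' Derive feed efficiency from gain and intake
#'
#' Feed efficiency is the ratio of test daily gain to daily feed intake on a
#' common unit basis. The field convention varies on whether intake is
#' recorded in g/d or kg/d, so the basis is explicit: with
#' `basis = "g_per_d"` both TDG and DFI are taken as g/d and FE is the
#' dimensionless gain:feed ratio; with `basis = "kg_dfi"` DFI is taken as
#' kg/d and converted to g/d before dividing.
#'
#' @param perf Performance `data.frame` with `TDG` and `DFI` columns.
#' @param basis Unit basis for DFI, `"g_per_d"` (default) or `"kg_dfi"`.
#' @param recompute If `FALSE` (default) rows with an existing FE value keep
#'   it; if `TRUE` FE is recomputed wherever possible.
#' @return The data frame with the `FE` column populated. Rows where TDG or
#'   DFI is missing (or DFI is zero) keep a missing FE and trigger one
#'   warning.
#' @export
derive_feed_efficiency <- function(perf, basis = c("g_per_d", "kg_dfi"),
                                   recompute = FALSE) {
  basis <- match.arg(basis)
  if (!"FE" %in% names(perf)) perf$FE <- NA_real_
  dfi <- perf$DFI
  if (basis == "kg_dfi") dfi <- dfi * 1000
  can <- !is.na(perf$TDG) & !is.na(dfi) & dfi > 0
  target <- if (recompute) can else can & is.na(perf$FE)
  perf$FE[target] <- perf$TDG[target] / dfi[target]
  skipped <- (!can) & is.na(perf$FE)
  if (any(skipped))
    warning(sprintf("FE left missing for %d animal(s): TDG or DFI missing or DFI zero",
                    sum(skipped)))
  perf
}

#' Read a three-column pedigree file
#'
#' Unknown parents are coded 0 (the empty string is accepted as a synonym).
#' Rows may appear in any order; the pedigree is topologically sorted so that
#' parents precede offspring, with ties broken by file order, and ids are
#' recoded to consecutive integers. Original labels are retained.
#'
#' @param path CSV with columns `animal,sire,dam`.
#' @return A `pedigree` object (see [as_pedigree()]).
#' @export
read_pedigree <- function(path) {
  df <- read_csv_checked(path, c("animal", "sire", "dam"))
  as_pedigree(df)
}

#' Write posterior summary tables
#'
#' Writes the standard result set: the per-trait variance-ratio table
#' (`h2_table.csv`), the SNA-by-SNA genetic correlation table
#' (`rg_sna.csv`), the SNA-by-performance genetic correlation table
#' (`rg_sna_perf.csv`) and the Spearman phenotypic correlation matrix
#' (`rp_spearman.csv`). Missing components are written as empty files with
#' headers so downstream consumers always find the full set.
#'
#' @param summaries List with (any of) elements `h2` (data frame from
#'   [summarize_univariate()]), `rg_sna`, `rg_sna_perf` (data frames from
#'   [summarize_bivariate()]) and `rp` (matrix from [spearman_matrix()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results_tables <- function(summaries, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)

  h2 <- summaries$h2
  if (is.null(h2))
    h2 <- empty_df(c("trait", "h2_mean", "h2_lo", "h2_hi", "c2_mean", "c2_lo",
                     "c2_hi", "Vp_mean", "Vp_lo", "Vp_hi", "geweke_z"))
  p <- file.path(dir, "h2_table.csv")
  write_csv_plain(h2, p); paths <- c(paths, p)

  for (nm in c("rg_sna", "rg_sna_perf")) {
    tab <- summaries[[nm]]
    if (is.null(tab))
      tab <- empty_df(c("trait_a", "trait_b", "rg_mean", "rg_lo", "rg_hi",
                        "significant"))
    p <- file.path(dir, paste0(nm, ".csv"))
    write_csv_plain(tab, p); paths <- c(paths, p)
  }

  rp <- summaries$rp
  if (!is.null(rp)) {
    p <- file.path(dir, "rp_spearman.csv")
    df <- data.frame(trait = rownames(rp), as.data.frame(rp),
                     check.names = FALSE)
    write_csv_plain(df, p); paths <- c(paths, p)
  }
  invisible(paths)
}

# ---- internal helpers -------------------------------------------------------

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(basename(path), ": missing required column(s): ",
         paste(missing, collapse = ", "))
  df[required]
}

# 12 significant digits so write -> read round-trips within float formatting
write_csv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (cn in names(df)[num]) {
    out[[cn]] <- ifelse(is.na(df[[cn]]), "",
                        formatC(df[[cn]], digits = 12, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

empty_df <- function(cols) {
  df <- as.data.frame(stats::setNames(replicate(length(cols), character(0),
                                                simplify = FALSE), cols))
  df
}
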