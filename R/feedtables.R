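# Data model, CSV schemas and bundled fixtures for the rapeseed-cake
# digestibility tables. All bundled concentrations are air-dry basis
# percentages unless a column name says otherwise (GE in MJ/kg, total
# glucosinolates in umol/g, digesta assays in g/kg DM).

#' Canonical component labels
#'
#' Proximate components, the 18 analyzed amino acids, and crude protein as
#' used throughout the package. `aa_components()` returns the amino acids in
#' the order they appear in the composition tables (essential first).
#'
#' @return Character vector of component labels.
#' @export
proximate_components <- function() {
  c("DM", "GE", "CP", "EE", "Ash", "CF", "NDF", "ADF", "Ca", "TP", "TGS")
}

#' @rdname proximate_components
#' @export
aa_components <- function() {
  c("Arg", "His", "Ile", "Leu", "Lys", "Met", "Phe", "Thr", "Trp", "Val",
    "Ala", "Asp", "Cys", "Glu", "Gly", "Pro", "Ser", "Tyr")
}

# lowercase CSV column name for each amino acid
.aa_cols <- function() stats::setNames(tolower(aa_components()), aa_components())

# map ingredient CSV columns to canonical proximate labels
.prox_cols <- c(DM = "dm", GE = "ge_mj_kg", CP = "cp", EE = "ee", Ash = "ash",
                CF = "cf", NDF = "ndf", ADF = "adf", Ca = "ca", TP = "tp",
                TGS = "tgs_umol_g")

.schemas <- function() {
  aa <- unname(.aa_cols())
  list(
    ingredients = list(
      cols = c("sample_id", "color", "heat_mid_c", "heat_halfrange_c",
               "heat_min", "origin", unname(.prox_cols), aa),
      character = c("sample_id", "color", "origin")),
    diets = list(
      cols = c("diet_id", "dm", "cp", "marker_pct", aa),
      character = "diet_id"),
    digesta = list(
      cols = c("pig_id", "period", "diet_id", "marker_g_kg_dm", "cp", aa),
      character = c("pig_id", "diet_id")),
    endogenous = list(
      cols = c("component", "g_kg_dmi"),
      character = "component")
  )
}

.coerce_numeric <- function(df, cols, path) {
  for (cl in cols) {
    raw <- df[[cl]]
    blank <- is.na(raw) | !nzchar(trimws(raw))
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(num))
    if (length(bad)) {
      stop(sprintf("parse error in '%s': non-numeric value \"%s\" at row %d, column '%s'",
                   basename(path), raw[bad[1]], bad[1], cl), call. = FALSE)
    }
    df[[cl]] <- num
  }
  df
}

.validate_records <- function(df, schema) {
  fail <- function(msg) stop("validation error: ", msg, call. = FALSE)
  nonneg <- function(cols) {
    for (cl in cols) {
      v <- df[[cl]]
      if (any(!is.na(v) & v < 0)) fail(sprintf("negative concentration in column '%s'", cl))
    }
  }
  aa <- unname(.aa_cols())
  if (schema == "ingredients") {
    nonneg(c(unname(.prox_cols), aa))
    if (any(df$dm <= 0 | df$dm > 100)) fail("dm must lie in (0, 100]")
    if (any(df$heat_mid_c <= 0)) fail("heat_mid_c must be positive")
    if (any(df$cp >= df$dm)) fail("cp must be below dm")
    over <- df[aa] >= df$cp
    if (any(over, na.rm = TRUE)) fail("every amino acid concentration must be below cp")
  } else if (schema == "diets") {
    nonneg(c("cp", aa))
    if (any(df$dm <= 0 | df$dm > 100)) fail("dm must lie in (0, 100]")
    if (any(df$marker_pct <= 0)) fail("marker_pct must be positive")
  } else if (schema == "digesta") {
    nonneg(c("cp", aa))
    if (any(df$marker_g_kg_dm <= 0)) fail("marker_g_kg_dm must be positive")
    if (any(df$period != as.integer(df$period) | df$period < 1))
      fail("period must be a positive integer")
    df$period <- as.integer(df$period)
  } else if (schema == "endogenous") {
    if (any(df$g_kg_dmi < 0)) fail("endogenous losses must be nonnegative")
  }
  df
}

#' Read or write a feed-trial table
#'
#' CSV readers/writers for the four table schemas used by the pipeline:
#' `ingredients` (one rapeseed-cake lot per row: provenance, heating regime,
#' proximate and amino-acid composition, air-dry basis), `diets` (analyzed
#' diet composition plus DM and TiO2 marker inclusion, air-dry), `digesta`
#' (one pig-period ileal digesta assay per row, g/kg DM), and `endogenous`
#' (basal ileal losses in g/kg DM intake). Missing assays are empty cells and
#' come back as `NA`, never zero. Row order is preserved and invariants
#' (positive DM and marker, nonnegative concentrations, CP below DM) are
#' enforced on read.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"ingredients"`, `"diets"`, `"digesta"`, `"endogenous"`.
#' @return `read_feed_table()`: a validated `data.frame`.
#' @export
read_feed_table <- function(path, schema = c("ingredients", "diets", "digesta", "endogenous")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- .schemas()[[schema]]
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = TRUE,
                    strip.white = TRUE),
    error = function(e) stop(sprintf("schema error: cannot read '%s' (%s)",
                                     basename(path), conditionMessage(e)), call. = FALSE))
  missing <- setdiff(sc$cols, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in '%s': missing column(s) %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[sc$cols]
  df <- .coerce_numeric(df, setdiff(sc$cols, sc$character), path)
  for (cl in sc$character) df[[cl]][!nzchar(df[[cl]])] <- NA_character_
  .validate_records(df, schema)
}

#' @param x A `data.frame` conforming to the schema.
#' @rdname read_feed_table
#' @return `write_feed_table()`: the path, invisibly.
#' @export
write_feed_table <- function(x, path, schema = c("ingredients", "diets", "digesta", "endogenous")) {
  schema <- match.arg(schema)
  sc <- .schemas()[[schema]]
  missing <- setdiff(sc$cols, names(x))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(x[sc$cols], path, row.names = FALSE, na = "")
  invisible(path)
}

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "rscdigest")
  if (!nzchar(p)) stop("bundled fixture not found: ", file, call. = FALSE)
  p
}

#' Bundled feed-evaluation tables
#'
#' The published tables for the ten rapeseed-cake (RSC) lots, transcribed as
#' plain CSV and returned as validated data frames:
#' \describe{
#'   \item{ingredients}{10 lots: provenance, heating midpoint (degrees C) and
#'     duration (min), proximate and amino-acid composition (air-dry).}
#'   \item{diets}{11 analyzed diets (10 RSC test diets at 40% inclusion plus
#'     the nitrogen-free diet `NFREE`), DM, CP, amino acids and the 0.30%
#'     TiO2 marker, air-dry.}
#'   \item{endogenous}{Named vector of basal ileal endogenous losses,
#'     g/kg DM intake (CP plus 18 amino acids).}
#'   \item{aid, sid}{Treatment-mean apparent and standardized ileal
#'     digestibility (%) per component and lot, with the reported pooled SEM
#'     and ANOVA p-value; `aid_letters`/`sid_letters` carry the reported
#'     pairwise-comparison letter groups.}
#'   \item{composition_printed}{The reported across-lot Mean and CV columns,
#'     kept separate from the per-lot rows: the EE, TGS and TP CVs cannot be
#'     recomputed from the printed rows and are stored as reported, not
#'     reconciled.}
#' }
#'
#' @return A named list of data frames (and a named numeric vector for
#'   `endogenous`).
#' @export
rsc_fixtures <- function() {
  endo <- read_feed_table(.extdata("endogenous.csv"), "endogenous")
  read_wide <- function(file) {
    utils::read.csv(.extdata(file), check.names = FALSE,
                    colClasses = c(component = "character"))
  }
  list(
    ingredients = read_feed_table(.extdata("ingredients.csv"), "ingredients"),
    diets = read_feed_table(.extdata("diets.csv"), "diets"),
    endogenous = stats::setNames(endo$g_kg_dmi, endo$component),
    aid = read_wide("aid.csv"),
    aid_letters = utils::read.csv(.extdata("aid_letters.csv"), check.names = FALSE,
                                  colClasses = "character", na.strings = NULL),
    sid = read_wide("sid.csv"),
    sid_letters = utils::read.csv(.extdata("sid_letters.csv"), check.names = FALSE,
                                  colClasses = "character", na.strings = NULL),
    composition_printed = read_wide("composition_printed.csv")
  )
}

#' Predictor table for the regression stage
#'
#' Arranges one row per rapeseed-cake lot with the candidate predictors used
#' for correlation and stepwise regression: the proximate components (DM, GE,
#' CP, EE, Ash, CF, NDF, ADF, Ca, TP, TGS) plus the processing-heat midpoint
#' `HT` in degrees C.
#'
#' @param ingredients An ingredients table as returned by
#'   [read_feed_table()] or [rsc_fixtures()].
#' @return A `data.frame` with rownames `sample_id`.
#' @export
predictor_table <- function(ingredients) {
  out <- ingredients[unname(.prox_cols)]
  names(out) <- names(.prox_cols)
  out$HT <- ingredients$heat_mid_c
  rownames(out) <- ingredients$sample_id
  out
}
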