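# Analyte panel registry: quantification limits, units, class, panel label.

# Reference summary statistics for the 45 CVL analytes plus total protein:
# published medians (healthy visits), between-/within-woman SDs of log10
# concentration (sd_b, sd_w), the published ICC, the fraction of healthy
# visits above the LLOQ, and the number of healthy visits at which the
# analyte was measured (assay subsets: 370, 302, 301 or 230).
.panel_reference <- function() {
  tribble(
    ~analyte,    ~class,                      ~units,  ~panel, ~n_measured, ~median_ref, ~sd_b, ~icc_ref, ~sd_w, ~detect_ref,
    "IL-1a",     "inflammatory cytokine",     "pg/ml", "a",    370,  24.7,     0.35, 0.51, 0.35, 1.00,
    "IL-1b",     "inflammatory cytokine",     "pg/ml", "a",    370,  17.0,     0.58, 0.52, 0.55, 0.93,
    "IL-6",      "inflammatory cytokine",     "pg/ml", "a",    370,  14.2,     0.50, 0.48, 0.53, 0.95,
    "IL-12",     "inflammatory cytokine",     "pg/ml", "a",    370,  11.5,     0.46, 0.55, 0.42, 0.77,
    "IL-18",     "inflammatory cytokine",     "pg/ml", "c",    301,  21960.0,  0.54, 0.46, 0.58, 0.92,
    "TNF-a",     "inflammatory cytokine",     "pg/ml", "a",    370,  1.0,      0.36, 0.52, 0.35, 0.41,
    "IL-10",     "anti-inflammatory cytokine","pg/ml", "c",    301,  55.3,     0.34, 0.43, 0.39, 0.86,
    "IFN-g",     "adaptive cytokine",         "pg/ml", "a",    370,  7.1,      0.31, 0.42, 0.37, 0.36,
    "IL-2",      "adaptive cytokine",         "pg/ml", "a",    370,  24.8,     0.30, 0.55, 0.27, 0.93,
    "IL-4",      "adaptive cytokine",         "pg/ml", "a",    370,  2.8,      0.25, 0.40, 0.31, 0.49,
    "IL-15",     "adaptive cytokine",         "pg/ml", "a",    370,  0.8,      0.33, 0.57, 0.29, 0.44,
    "IL-16",     "adaptive cytokine",         "pg/ml", "a",    370,  67.5,     0.36, 0.50, 0.36, 0.69,
    "IL-17",     "adaptive cytokine",         "pg/ml", "c",    301,  32.7,     0.45, 0.49, 0.46, 0.82,
    "MIP-1a",    "CC chemokine",              "pg/ml", "b",    370,  7.8,      0.27, 0.41, 0.33, 0.60,
    "MIP-1b",    "CC chemokine",              "pg/ml", "b",    370,  23.1,     0.30, 0.41, 0.37, 0.89,
    "MCP-1",     "CC chemokine",              "pg/ml", "b",    370,  14.8,     0.38, 0.31, 0.57, 0.88,
    "MCP-2",     "CC chemokine",              "pg/ml", "b",    370,  8.4,      0.33, 0.44, 0.38, 0.63,
    "RANTES",    "CC chemokine",              "pg/ml", "b",    370,  4.0,      0.52, 0.54, 0.48, 0.86,
    "IP-10",     "CXC chemokine",             "pg/ml", "b",    370,  287.5,    0.42, 0.52, 0.41, 0.99,
    "SDF-1b",    "CXC chemokine",             "pg/ml", "b",    370,  71.7,     0.30, 0.51, 0.30, 0.41,
    "MIG",       "CXC chemokine",             "pg/ml", "b",    370,  5354.9,   0.58, 0.61, 0.46, 0.75,
    "IL-8",      "CXC chemokine",             "pg/ml", "b",    370,  491.1,    0.37, 0.46, 0.40, 1.00,
    "GM-CSF",    "growth factor",             "pg/ml", "b",    370,  4.4,      0.31, 0.49, 0.32, 0.95,
    "G-CSF",     "growth factor",             "pg/ml", "b",    370,  30.4,     0.50, 0.55, 0.45, 0.92,
    "TGF-a",     "growth factor",             "pg/ml", "c",    370,  40.1,     0.33, 0.57, 0.28, 0.89,
    "TGF-b",     "growth factor",             "pg/ml", "b",    370,  104.3,    0.34, 0.37, 0.45, 0.99,
    "IFN-b",     "antimicrobial protein",     "ng/ml", "b",    370,  0.3,      0.42, 0.42, 0.50, 0.64,
    "SLPI",      "antimicrobial protein",     "ng/ml", "e",    370,  238.5,    0.28, 0.33, 0.40, 1.00,
    "Elafin",    "antimicrobial protein",     "ng/ml", "e",    370,  107.0,    0.22, 0.41, 0.26, 1.00,
    "s100a8",    "antimicrobial protein",     "ng/ml", "e",    302,  9.9,      0.21, 0.37, 0.27, 1.00,
    "HNP1-3",    "antimicrobial protein",     "ng/ml", "e",    370,  342.9,    0.45, 0.38, 0.57, 1.00,
    "HBD2",      "antimicrobial protein",     "ng/ml", "e",    302,  446.2,    0.49, 0.38, 0.62, 0.95,
    "HBD3",      "antimicrobial protein",     "ng/ml", "c",    301,  7.8,      0.57, 0.32, 0.83, 0.97,
    "HBD4",      "antimicrobial protein",     "ng/ml", "e",    302,  0.4,      0.32, 0.49, 0.33, 0.86,
    "pIgR",      "immunoglobulin",            "ng/ml", "c",    301,  68.9,     0.41, 0.42, 0.49, 0.99,
    "IgA",       "immunoglobulin",            "ng/ml", "d",    230,  401.1,    0.37, 0.36, 0.50, 0.96,
    "IgM",       "immunoglobulin",            "ng/ml", "d",    230,  137.6,    0.51, 0.44, 0.57, 0.75,
    "IgG1",      "immunoglobulin",            "ng/ml", "d",    230,  9123.7,   0.23, 0.14, 0.57, 0.99,
    "IgG2",      "immunoglobulin",            "ng/ml", "d",    230,  3963.0,   0.41, 0.48, 0.43, 0.90,
    "IgG3",      "immunoglobulin",            "ng/ml", "d",    230,  312.3,    0.33, 0.20, 0.67, 0.97,
    "IgG4",      "immunoglobulin",            "ng/ml", "d",    230,  80.7,     0.71, 0.68, 0.48, 0.90,
    "APOA1",     "control",                   "ng/ml", "c",    302,  0.04,     0.65, 0.36, 0.86, 1.00,
    "SCCA-1",    "control",                   "ng/ml", "c",    301,  122.7,    0.36, 0.31, 0.55, 0.97,
    "Albumin",   "control",                   "ng/ml", "e",    302,  1802.4,   0.38, 0.46, 0.42, 1.00,
    "Involucrin","control",                   "ng/ml", "e",    302,  50.1,     0.47, 0.46, 0.51, 1.00,
    "Total protein", "total protein",         "ng/ml", "Bradford", 370, 123290.0, 0.19, 0.42, 0.22, 1.00
  )
}

.analyte_classes <- c(
  "inflammatory cytokine", "anti-inflammatory cytokine", "adaptive cytokine",
  "CC chemokine", "CXC chemokine", "growth factor", "antimicrobial protein",
  "immunoglobulin", "control", "total protein"
)

#' Default analyte panel
#'
#' The registry of the 45 soluble immune proteins plus total protein measured
#' in the CVL panel, with class, units, Luminex panel label and
#' quantification limits.
#'
#' Assay LLOQ/ULOQ values were not published; the limits shipped here are
#' *synthetic* plausible values derived from the published per-analyte
#' medians, log10-scale variance components and detection fractions under a
#' log-normal model. The LLOQ is placed at the latent quantile that
#' reproduces the published fraction of measurements above the LLOQ; the
#' ULOQ at the 99.5th percentile. The latent log10 mean `mu` is backed out
#' of the published median of *quantified* values by undoing the LLOQ
#' truncation.
#'
#' @return A tibble with one row per analyte and columns `analyte`, `class`,
#'   `units`, `panel`, `n_measured`, `median_ref`, `sd_b`, `icc_ref`,
#'   `sd_w`, `detect_ref`, `mu`, `lloq`, `uloq`.
#' @examples
#' panel <- default_panel()
#' nrow(panel)   # 46 entries
#' @export
default_panel <- function() {
  ref <- .panel_reference()
  sigma <- sqrt(ref$sd_b^2 + ref$sd_w^2)
  # median of values above the LLOQ sits at latent quantile 1 - detect/2
  mu <- log10(ref$median_ref) - sigma * qnorm(1 - ref$detect_ref / 2)
  det <- pmin(ref$detect_ref, 0.999)
  lloq <- 10^(mu + qnorm(1 - det) * sigma)
  uloq <- 10^(mu + qnorm(0.995) * sigma)
  out <- ref %>%
    mutate(mu = mu, lloq = lloq, uloq = uloq)
  validate_panel(out)
  out
}

#' Validate an analyte panel
#'
#' Checks the panel invariants: unique analyte names within a panel label,
#' positive limits with `lloq < uloq`, known analyte class, and units.
#'
#' @param panel A panel tibble (see [default_panel()]).
#' @return The panel, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_panel <- function(panel) {
  required <- c("analyte", "class", "units", "panel", "lloq", "uloq")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  dup <- panel %>% count(.data$panel, .data$analyte) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate analyte name(s) within a panel: ",
                 paste(dup$analyte, collapse = ", ")))
  }
  bad_lim <- which(is.na(panel$lloq) | is.na(panel$uloq) |
                     panel$lloq <= 0 | panel$lloq >= panel$uloq)
  if (length(bad_lim) > 0) {
    abort(paste0("invalid quantification limits (need 0 < lloq < uloq) in row(s): ",
                 paste(bad_lim, collapse = ", "),
                 " (", paste(panel$analyte[bad_lim], collapse = ", "), ")"))
  }
  bad_class <- which(!panel$class %in% .analyte_classes)
  if (length(bad_class) > 0) {
    abort(paste0("unknown analyte class in row(s): ",
                 paste(bad_class, collapse = ", "),
                 " (", paste(unique(panel$class[bad_class]), collapse = ", "), ")"))
  }
  bad_units <- which(!panel$units %in% c("pg/ml", "ng/ml"))
  if (length(bad_units) > 0) {
    abort(paste0("units must be pg/ml or ng/ml; offending row(s): ",
                 paste(bad_units, collapse = ", ")))
  }
  invisible(panel)
}

#' Load an analyte panel from a configuration file
#'
#' Reads a panel registry from YAML (a list of records) or CSV, validates it
#' and returns it keyed by analyte name. An empty file yields an empty
#' registry with a warning.
#'
#' @param path Path to a `.yml`/`.yaml` or `.csv` panel configuration with
#'   fields `analyte`, `class`, `units`, `panel`, `lloq`, `uloq`.
#' @return A validated panel tibble.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    recs <- yaml::read_yaml(path)
    if (length(recs) == 0) {
      warn("empty panel file; returning empty registry")
      return(tibble(analyte = character(), class = character(),
                    units = character(), panel = character(),
                    lloq = numeric(), uloq = numeric()))
    }
    panel <- map_dfr(recs, function(r) {
      as_tibble(r[c("analyte", "class", "units", "panel", "lloq", "uloq")])
    })
  } else {
    panel <- readr::read_csv(path, show_col_types = FALSE)
    if (nrow(panel) == 0) {
      warn("empty panel file; returning empty registry")
      return(panel)
    }
  }
  validate_panel(panel)
  panel
}

#' Write a panel registry to CSV
#' @param panel Panel tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}
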