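#' Covariate definition
#'
#' One row of a covariate catalog: a short code, free-text description, units,
#' kind (continuous or categorical), and the covariate-set labels (C1..C7) the
#' variable belongs to when assembling model variants.
#'
#' @param name Short covariate code, e.g. `"Marsh_Elev"`. Must be unique
#'   within a catalog.
#' @param description Free text.
#' @param units One of `"cm"`, `"m"`, `"ha"`, `"%"`, `"degrees"`,
#'   `"categorical"`.
#' @param kind `"continuous"` or `"categorical"`.
#' @param sets Character vector, subset of `C1`..`C7`.
#' @param levels For categorical covariates, the finite label vocabulary
#'   (required); ignored for continuous covariates.
#' @return A one-row `data.frame` with list-columns `sets` and `levels`.
#' @export
covariate_def <- function(name, description = "", units = "m",
                          kind = c("continuous", "categorical"),
                          sets = character(), levels = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  units <- match.arg(units, c("cm", "m", "ha", "%", "degrees", "categorical"))
  if (length(sets) && !all(sets %in% paste0("C", 1:7)))
    stop("covariate sets must be drawn from C1..C7")
  if (kind == "categorical" && (is.null(levels) || !length(levels)))
    stop("categorical covariate '", name, "' needs an explicit level vocabulary")
  out <- data.frame(name = name, description = description, units = units,
                    kind = kind, stringsAsFactors = FALSE)
  out$sets <- list(sets)
  out$levels <- list(if (kind == "categorical") as.character(levels) else character())
  out
}

#' Build a covariate catalog
#'
#' @param ... `covariate_def()` rows.
#' @return A `covariate_catalog` data.frame. Names must be unique.
#' @export
covariate_catalog <- function(...) {
  cat <- do.call(rbind, list(...))
  if (anyDuplicated(cat$name))
    stop("duplicate covariate names in catalog: ",
         paste(cat$name[duplicated(cat$name)], collapse = ", "))
  class(cat) <- c("covariate_catalog", "data.frame")
  cat
}

#' @export
print.covariate_catalog <- function(x, ...) {
  cat("Covariate catalog:", nrow(x), "covariates\n")
  df <- data.frame(name = x$name, units = x$units, kind = x$kind,
                   sets = vapply(x$sets, paste, "", collapse = ","))
  print(df, row.names = FALSE)
  invisible(x)
}

# Outcome vocabulary. TRAP = trap set, no capture; the other nine labels are
# the capture states of the all-species response. RE is the genus-level
# Reithrodontomys record that could not be assigned to species.
.species_states <- c("MICA", "MUMU", "PEMA", "RANO", "RARA",
                     "RE", "REME", "RERA", "SOOR")

#' Outcome label vocabulary
#'
#' The ten trap-night outcome labels: nine capture species codes plus
#' `"TRAP"` (no capture).
#' @return Character vector of length 10.
#' @export
outcome_labels <- function() c("TRAP", .species_states)

#' Response specification
#'
#' The analysis uses two response variables: presence of the salt marsh
#' harvest mouse (`rera_presence`, states RERA / NOTRERA) and the capture
#' species itself (`all_species`, nine states).
#'
#' @param mode `"rera_presence"` or `"all_species"`.
#' @return A `response_spec` list with elements `mode` and `states`.
#' @export
response_spec <- function(mode = c("rera_presence", "all_species")) {
  mode <- match.arg(mode)
  states <- if (mode == "rera_presence") c("RERA", "NOTRERA") else .species_states
  structure(list(mode = mode, states = states), class = "response_spec")
}

#' Default covariate catalog for the trap-survey analysis
#'
#' Covariates of the marsh small-mammal survey: trap-design variables (C1),
#' coordinates (C2), vegetation of the one to three most dominant cover
#' categories (C3, C4), elevation and tidal-datum variables (C5), distances to
#' natural and anthropogenic features (C6), and marsh patch sizes (C7).
#'
#' Set membership mirrors the model-variant table: C3 is the dominant plant's
#' identity, percent cover, maximum and average height; C4 adds the same four
#' variables for the second and third most dominant categories; C5 holds four
#' elevation variables (MHHW itself is screened out before modelling); C6 the
#' four retained distance variables.
#'
#' @param sites Site label vocabulary used for the categorical `site` design
#'   covariate.
#' @return A `covariate_catalog`.
#' @export
default_catalog <- function(sites = default_site_names()) {
  plants <- c("pickleweed", "bare", "saltgrass", "alkali_heath", "other")
  veg <- function(prefix, set) {
    rbind(
      covariate_def(paste0(prefix, "_Dom"), "dominant cover category",
                    "categorical", "categorical", set, levels = plants),
      covariate_def(paste0(prefix, "_V_PERC"), "percent cover of the category",
                    "%", "continuous", set),
      covariate_def(paste0(prefix, "_V1_MAX"), "maximum height of the category",
                    "cm", "continuous", set),
      covariate_def(paste0(prefix, "_V1_AVG"), "average height of the category",
                    "cm", "continuous", set))
  }
  covariate_catalog(
    covariate_def("site", "study site", "categorical", "categorical", "C1",
                  levels = sites),
    covariate_def("year", "survey year", "categorical", "categorical", "C1",
                  levels = as.character(1998:2014)),
    covariate_def("session", "trapping session within year", "categorical",
                  "categorical", "C1", levels = c("spring", "summer", "fall")),
    covariate_def("layout", "trap layout pattern", "categorical", "categorical",
                  "C1", levels = c("grid", "transect", "random")),
    covariate_def("trap_id", "trap position within site", "categorical",
                  "categorical", "C1", levels = paste0("T", 1:999)),
    covariate_def("latitude", "trap latitude", "degrees", "continuous", "C2"),
    covariate_def("longitude", "trap longitude", "degrees", "continuous", "C2"),
    veg("P1", c("C3", "C4")), veg("P2", "C4"), veg("P3", "C4"),
    covariate_def("Marsh_Elev", "marsh elevation at the trap, from DEM", "cm",
                  "continuous", "C5"),
    covariate_def("MHW", "mean high water level", "m", "continuous", "C5"),
    covariate_def("Elev_MHW", "trap elevation relative to MHW", "m",
                  "continuous", "C5"),
    covariate_def("MHHW", "mean higher high water level", "m", "continuous",
                  character()),
    covariate_def("Elev_MHHW", "trap elevation relative to MHHW", "m",
                  "continuous", "C5"),
    covariate_def("Dist_Levee", "distance to closest levee", "m", "continuous",
                  "C6"),
    covariate_def("Dist_Water", "distance to closest water", "m", "continuous",
                  "C6"),
    covariate_def("Dist_Bay", "distance to bay", "m", "continuous", "C6"),
    covariate_def("Dist_Urban", "distance to closest urban area", "m",
                  "continuous", character()),
    covariate_def("Dist_Ag", "distance to closest agriculture", "m",
                  "continuous", character()),
    covariate_def("Dist_Road", "distance to closest paved road", "m",
                  "continuous", "C6"),
    covariate_def("Patch_Size",
                  "continuous marsh patch not impeded by barriers, channels >3 m, or levees",
                  "ha", "continuous", "C7"),
    covariate_def("Patch_Size_Expanded",
                  "continuous marsh patch not impeded by barriers or channels >3 m",
                  "ha", "continuous", "C7"))
}

#' Default site names
#' @return Character vector of the six study-site labels.
#' @export
default_site_names <- function() {
  c("Benicia-Martinez", "Corte Madera", "Fagan", "Guadalcanal",
    "Tolay Creek", "Tubbs Setback")
}

#' The 13 continuous landscape covariates entering correlation screening
#'
#' Elevation, tidal-datum, distance, and patch-size variables; vegetation
#' covariates are excluded from screening because of their sparsity.
#' @return Character vector of 13 covariate names.
#' @export
screening_covariates <- function() {
  c("Marsh_Elev", "MHW", "Elev_MHW", "MHHW", "Elev_MHHW",
    "Dist_Levee", "Dist_Water", "Dist_Bay", "Dist_Urban", "Dist_Ag",
    "Dist_Road", "Patch_Size", "Patch_Size_Expanded")
}

#' Published survey margins
#'
#' The study's printed effort and outcome margins, usable as inputs: trap
#' nights by year and site, trap nights by site and layout, and capture
#' outcomes by species and site. These drive margin reconstructions and the
#' always-nonpresence baseline without any download.
#'
#' @return A list with data.frames `effort` (year x site trap nights),
#'   `layout` (site x layout trap nights), and `captures` (species x site
#'   capture counts, plus a `TRAP` row of no-capture nights).
#' @export
study_margins <- function() {
  sites <- default_site_names()
  effort <- data.frame(
    year = c(1998:2011, 2014),
    `Benicia-Martinez` = c(0,0,0,0,0,0,0,0,225,225,195,0,0,0,0),
    `Corte Madera`     = c(0,0,0,0,0,0,0,0,0,0,0,0,0,0,150),
    Fagan              = c(0,0,0,0,0,0,0,0,0,0,0,0,0,300,0),
    Guadalcanal        = c(0,0,0,0,0,225,0,195,225,225,0,0,0,0,0),
    `Tolay Creek`      = c(600,2270,634,330,660,660,618,588,225,300,225,225,225,0,0),
    `Tubbs Setback`    = c(0,0,0,0,0,360,360,360,360,360,360,0,360,360,0),
    check.names = FALSE)
  layout <- data.frame(
    site = sites,
    grid = c(225, 0, 300, 300, 6840, 0),
    random = c(0, 0, 0, 0, 0, 2520),
    transect = c(420, 150, 0, 570, 720, 360))
  captures <- data.frame(
    species = c(.species_states, "TRAP"),
    `Benicia-Martinez` = c(0,22,0,0,0,0,0,0,0, 623),
    `Corte Madera`     = c(0,1,0,0,0,3,1,0,0, 145),
    Fagan              = c(16,10,0,0,0,0,0,22,1, 251),
    Guadalcanal        = c(2,156,0,0,0,0,0,19,0, 693),
    `Tolay Creek`      = c(1437,211,181,4,0,0,33,546,63, 5085),
    `Tubbs Setback`    = c(110,155,252,10,1,0,0,82,1, 2269),
    check.names = FALSE)
  list(effort = effort, layout = layout, captures = captures)
}
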