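#' The gastrointestinal-cancer readmission study variables
#'
#' Eight categorical variables describe each patient in the readmission
#' analysis: cancer site group (`CANCER`), body-mass-index class (`BMI`),
#' bone metastasis (`MTX`), serum-albumin class (`ALB`), nutritional support
#' (`NUTR`), breakthrough-cancer-pain predictability (`BTcP`), radiotherapy
#' (`RADIO`), and the unplanned hospital-readmission count class (`HRA`,
#' the only ordered variable).
#'
#' @return `gi_variables()` returns a list of variable specifications, each a
#'   list with `name`, `levels`, and `ordered`; `gi_levels()` returns just the
#'   named list of level vectors.
#' @export
gi_variables <- function() {
  spec <- function(name, levels, ordered = FALSE)
    list(name = name, levels = levels, ordered = ordered)
  list(
    BMI    = spec("BMI",    c("<25", ">=25")),
    CANCER = spec("CANCER", c("Esophageal or gastric", "Colon-rectum",
                              "Pancreas, gallbladder, biliary tract")),
    MTX    = spec("MTX",    c("No", "Yes")),
    ALB    = spec("ALB",    c("<=3.5", ">3.5")),
    NUTR   = spec("NUTR",   c("No", "Yes")),
    BTcP   = spec("BTcP",   c("Not predictable", "Predictable")),
    RADIO  = spec("RADIO",  c("No", "Yes")),
    HRA    = spec("HRA",    c("<=10", "11-22", ">22"), ordered = TRUE)
  )
}

#' @rdname gi_variables
#' @export
gi_levels <- function() lapply(gi_variables(), `[[`, "levels")

#' Reference network structures of the readmission analysis
#'
#' `gi_bic_dag()` is the 7-arc structure read off the BIC-selected
#' factorization
#' `P(BMI) P(ALB) P(CANCER) P(MTX|CANCER) P(NUTR|ALB) P(BTcP|MTX,BMI)
#'  P(RADIO|MTX) P(HRA|NUTR,RADIO)`.
#' `gi_knowledge_dag()` is the 11-arc hypothesized ("knowledge-based")
#' structure assembled from the clinically asserted pairwise associations,
#' with each arc oriented from cause to effect.
#'
#' @return a [bn_dag] on the 8 study variables.
#' @seealso [gi_constraints()], [graph_indicators()]
#' @export
gi_bic_dag <- function() {
  bn_dag(list(
    BMI    = character(0),
    ALB    = character(0),
    CANCER = character(0),
    MTX    = "CANCER",
    NUTR   = "ALB",
    BTcP   = c("MTX", "BMI"),
    RADIO  = "MTX",
    HRA    = c("NUTR", "RADIO")
  ), nodes = names(gi_variables()))
}

#' @rdname gi_bic_dag
#' @export
gi_knowledge_dag <- function() {
  bn_dag(list(
    BMI    = character(0),
    ALB    = character(0),
    CANCER = character(0),
    MTX    = "CANCER",
    NUTR   = c("CANCER", "MTX", "ALB", "RADIO"),
    BTcP   = c("BMI", "MTX"),
    RADIO  = "MTX",
    HRA    = c("CANCER", "NUTR", "RADIO")
  ), nodes = names(gi_variables()))
}

#' Clinical whitelist and blacklist for structure learning
#'
#' Prior clinical knowledge fixed before the search. Whitelisted (forced)
#' arcs: high BMI predisposes to breakthrough pain (`BMI -> BTcP`), bone
#' metastases induce breakthrough pain and palliative radiotherapy
#' (`MTX -> BTcP`, `MTX -> RADIO`), and low albumin drives nutritional
#' support (`ALB -> NUTR`). Blacklisted (impossible) arcs: nothing can cause
#' the tumor type (every arc into `CANCER`), and neither albumin nor
#' nutritional support can cause breakthrough pain or bone metastasis.
#'
#' @return a [bn_constraints] object.
#' @export
gi_constraints <- function() {
  vars <- names(gi_variables())
  into_cancer <- cbind(setdiff(vars, "CANCER"), "CANCER")
  bn_constraints(
    whitelist = rbind(c("BMI", "BTcP"),
                      c("MTX", "BTcP"),
                      c("MTX", "RADIO"),
                      c("ALB", "NUTR")),
    blacklist = rbind(into_cancer,
                      c("ALB", "BTcP"),
                      c("NUTR", "BTcP"),
                      c("ALB", "MTX"),
                      c("NUTR", "MTX"))
  )
}

#' Clinical discretization rules for the raw cohort table
#'
#' Cut points of clinical interest: BMI below vs at-or-above 25 kg/m2,
#' serum albumin at or below vs above 3.5 g/dL (the hypoalbuminemia
#' threshold), and the unplanned readmission count in three classes
#' (at most 10, 11 to 22, more than 22). Interval labels are taken
#' literally: 25.0 falls in the upper BMI class, 3.5 and 10 in the lower
#' albumin and readmission classes.
#'
#' @return a list of [discretization_rule()] objects keyed by raw column
#'   name (`bmi` in kg/m2, `albumin` in g/dL, `hra_count` in accesses).
#' @export
gi_discretization_rules <- function() {
  lv <- gi_levels()
  list(
    bmi = discretization_rule("bmi", output = "BMI", cuts = 25,
                              labels = lv$BMI, right = FALSE),
    albumin = discretization_rule("albumin", output = "ALB", cuts = 3.5,
                                  labels = lv$ALB, right = TRUE),
    hra_count = discretization_rule("hra_count", output = "HRA", cuts = c(10, 22),
                                    labels = lv$HRA, right = TRUE)
  )
}
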