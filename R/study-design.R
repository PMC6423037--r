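#' @import methods
NULL

# ---------------------------------------------------------------------------
# Classes
# ---------------------------------------------------------------------------

#' StudyDesign: the longitudinal treatment/sampling skeleton
#'
#' Encodes the multi-dose longitudinal experiment every other stage is indexed
#' against: group sizes, the biweekly dose schedule with one longer gap, the
#' milk-recording window and the transcriptomic sampling days. Study day 0 is
#' the day of the first dose; the conditioning (pre-dose) period runs on
#' negative days.
#'
#' @slot nControl Number of control animals.
#' @slot nTreated Number of treated animals.
#' @slot firstDoseDay Study day of the first dose (convention: 0).
#' @slot doseIntervalDays Days between consecutive doses (default 14).
#' @slot gapAfterDose 1-based dose index after which the long gap occurs
#'   (default 5); `NA` for no gap.
#' @slot gapDays Length of the long gap in days (default 28).
#' @slot nDoses Total number of doses (default 12).
#' @slot conditioningDays Days of pre-dose recording (default 18).
#' @slot followupDays Days of recording after the last dose (default 54).
#' @slot samplingDays Integer vector of study days on which milk somatic cells
#'   are sampled (36 days by default).
#' @slot doseAmountMg Dose in mg (metadata only; default 500).
#' @export
setClass("StudyDesign", representation(
  nControl = "integer", nTreated = "integer",
  firstDoseDay = "integer", doseIntervalDays = "integer",
  gapAfterDose = "integer", gapDays = "integer", nDoses = "integer",
  conditioningDays = "integer", followupDays = "integer",
  samplingDays = "integer", doseAmountMg = "numeric"
))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (object@nDoses < 1L) msg <- c(msg, "nDoses must be >= 1")
  if (object@doseIntervalDays < 1L) msg <- c(msg, "doseIntervalDays must be >= 1")
  if (is.unsorted(object@samplingDays, strictly = TRUE))
    msg <- c(msg, "samplingDays must be strictly increasing")
  if (!is.na(object@gapAfterDose) && object@gapDays < object@doseIntervalDays)
    msg <- c(msg, "gapDays must be >= doseIntervalDays")
  if (!is.na(object@gapAfterDose) &&
      (object@gapAfterDose < 1L || object@gapAfterDose >= object@nDoses) &&
      object@nDoses > 1L)
    msg <- c(msg, "gapAfterDose must lie between 1 and nDoses - 1")
  if (object@nControl < 1L || object@nTreated < 1L)
    msg <- c(msg, "both groups need at least one animal")
  if (length(msg)) msg else TRUE
})

#' DoseSchedule: the realised dose days
#'
#' @slot doseDays Strictly increasing integer vector of study days, one per
#'   dose; consecutive differences equal the dose interval except for the one
#'   configured gap.
#' @export
setClass("DoseSchedule", representation(doseDays = "integer"))

setValidity("DoseSchedule", function(object) {
  if (length(object@doseDays) >= 2L && is.unsorted(object@doseDays, strictly = TRUE))
    "doseDays must be strictly increasing" else TRUE
})

#' PlateLayout: a high-throughput qPCR plate design
#'
#' @slot nAssays Number of assays (genes) on the plate.
#' @slot nReplicates Technical replicates per assay and sample.
#' @slot nSamples Samples per plate.
#' @slot capacity Reaction capacity of the plate (default 3072).
#' @export
setClass("PlateLayout", representation(
  nAssays = "integer", nReplicates = "integer",
  nSamples = "integer", capacity = "integer"
))

setValidity("PlateLayout", function(object) {
  v <- c(object@nAssays, object@nReplicates, object@nSamples, object@capacity)
  if (any(v < 1L)) "all counts must be >= 1" else TRUE
})

# ---------------------------------------------------------------------------
# Constructors
# ---------------------------------------------------------------------------

# Default transcriptomic sampling grid: all study days named in the source
# experiment's text plus roughly weekly fill-in, 36 days spanning -10..219.
.defaultSamplingDays <- function() {
  as.integer(c(-10, 1, 2, 3, 7, 9, 14, 17, 21, 23, 28, 30, 35, 37, 44, 49,
               53, 57, 63, 70, 77, 84, 91, 98, 105, 112, 115, 126, 140, 154,
               168, 175, 189, 203, 212, 219))
}

#' Create a StudyDesign
#'
#' Defaults reproduce the reference experiment: 3 control and 6 treated cows,
#' 12 doses of 500 mg every 14 days with a single 28-day gap between doses 5
#' and 6, 18 conditioning days, 54 follow-up days and 36 sampling days.
#'
#' @param nControl,nTreated Group sizes.
#' @param firstDoseDay Study day of dose 1 (0 by convention).
#' @param doseIntervalDays Days between doses.
#' @param gapAfterDose Dose index after which the long gap occurs; `NA` disables
#'   the gap.
#' @param gapDays Length of the long gap.
#' @param nDoses Number of doses.
#' @param conditioningDays,followupDays Recording margins around the dosing
#'   period.
#' @param samplingDays Study days with transcriptomic sampling.
#' @param doseAmountMg Dose (metadata only).
#' @return A [StudyDesign-class] object.
#' @examples
#' d <- StudyDesign()
#' doseDays(buildDoseSchedule(d))[12] # day 168
#' @export
StudyDesign <- function(nControl = 3, nTreated = 6, firstDoseDay = 0,
                        doseIntervalDays = 14, gapAfterDose = 5, gapDays = 28,
                        nDoses = 12, conditioningDays = 18, followupDays = 54,
                        samplingDays = .defaultSamplingDays(),
                        doseAmountMg = 500) {
  new("StudyDesign",
      nControl = as.integer(nControl), nTreated = as.integer(nTreated),
      firstDoseDay = as.integer(firstDoseDay),
      doseIntervalDays = as.integer(doseIntervalDays),
      gapAfterDose = as.integer(gapAfterDose), gapDays = as.integer(gapDays),
      nDoses = as.integer(nDoses),
      conditioningDays = as.integer(conditioningDays),
      followupDays = as.integer(followupDays),
      samplingDays = as.integer(samplingDays),
      doseAmountMg = as.numeric(doseAmountMg))
}

#' Create a PlateLayout
#'
#' @param nAssays,nReplicates,nSamples,capacity Plate counts; defaults follow
#'   the 3072-reaction nanolitre plate with 18 assays in triplicate and 56
#'   samples.
#' @return A [PlateLayout-class] object.
#' @export
PlateLayout <- function(nAssays = 18, nReplicates = 3, nSamples = 56,
                        capacity = 3072) {
  new("PlateLayout", nAssays = as.integer(nAssays),
      nReplicates = as.integer(nReplicates), nSamples = as.integer(nSamples),
      capacity = as.integer(capacity))
}

# ---------------------------------------------------------------------------
# Accessors
# ---------------------------------------------------------------------------

#' @describeIn StudyDesign-class Number of control animals.
#' @param object,x A `StudyDesign`.
#' @export
setGeneric("nControl", function(object) standardGeneric("nControl"))
#' @export
setMethod("nControl", "StudyDesign", function(object) object@nControl)

#' @describeIn StudyDesign-class Number of treated animals.
#' @export
setGeneric("nTreated", function(object) standardGeneric("nTreated"))
#' @export
setMethod("nTreated", "StudyDesign", function(object) object@nTreated)

#' @describeIn StudyDesign-class Sampling days.
#' @export
setGeneric("samplingDays", function(object) standardGeneric("samplingDays"))
#' @export
setMethod("samplingDays", "StudyDesign", function(object) object@samplingDays)

#' Dose days of a DoseSchedule
#' @param object A `DoseSchedule`.
#' @export
setGeneric("doseDays", function(object) standardGeneric("doseDays"))
#' @export
setMethod("doseDays", "DoseSchedule", function(object) object@doseDays)

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", object@nControl, "control /", object@nTreated,
      "treated animals\n")
  cat("  doses:", object@nDoses, "x", object@doseAmountMg, "mg every",
      object@doseIntervalDays, "days")
  if (!is.na(object@gapAfterDose))
    cat(" (", object@gapDays, "-day gap after dose ", object@gapAfterDose,
        ")", sep = "")
  cat("\n  recording: -", object@conditioningDays, " .. last dose + ",
      object@followupDays, " days; ", length(object@samplingDays),
      " sampling days\n", sep = "")
})

setMethod("show", "DoseSchedule", function(object) {
  cat("DoseSchedule with", length(object@doseDays), "doses on days:\n  ")
  cat(object@doseDays, sep = ", ")
  cat("\n")
})

# ---------------------------------------------------------------------------
# Operations
# ---------------------------------------------------------------------------

#' Build the dose schedule implied by a StudyDesign
#'
#' Dose k (1-based) falls on `firstDoseDay + (k - 1) * doseIntervalDays`, with
#' `gapDays` substituted for the interval between dose `gapAfterDose` and the
#' next one. Under the defaults, dose 6 falls on day 84 and dose 12 on day 168.
#'
#' @param design A [StudyDesign-class].
#' @return A [DoseSchedule-class].
#' @export
buildDoseSchedule <- function(design) {
  stopifnot(is(design, "StudyDesign"))
  validObject(design)
  intervals <- rep(design@doseIntervalDays, max(design@nDoses - 1L, 0L))
  if (!is.na(design@gapAfterDose) && design@gapAfterDose < design@nDoses)
    intervals[design@gapAfterDose] <- design@gapDays
  new("DoseSchedule",
      doseDays = as.integer(design@firstDoseDay + c(0L, cumsum(intervals))))
}

#' Days since the most recent dose
#'
#' For each study day, the number of days elapsed since the most recent dose
#' (`NA` before the first dose). On a dose day the default semantics are
#' post-administration (`0`); `preAdministration = TRUE` instead refers to the
#' previous dose, which is the reading needed when a sample is drawn before
#' that day's injection (e.g. day 84 evaluates to 28, the length of the gap).
#'
#' @param schedule A [DoseSchedule-class].
#' @param day Integer vector of study days.
#' @param preAdministration Logical; see above.
#' @return Numeric vector, `NA` where undefined.
#' @export
daysSinceLastDose <- function(schedule, day, preAdministration = FALSE) {
  stopifnot(is(schedule, "DoseSchedule"))
  dd <- schedule@doseDays
  vapply(day, function(d) {
    prior <- if (preAdministration) dd[dd < d] else dd[dd <= d]
    if (length(prior) == 0L) NA_real_ else as.numeric(d - max(prior))
  }, numeric(1))
}

#' Length of the milk-recording window
#'
#' `conditioningDays + (last dose day - first dose day) + followupDays`;
#' 240 days under the default design.
#'
#' @param design A [StudyDesign-class].
#' @param schedule Optional [DoseSchedule-class]; built from `design` if
#'   missing.
#' @return Number of days.
#' @export
recordingSpan <- function(design, schedule = buildDoseSchedule(design)) {
  stopifnot(is(design, "StudyDesign"), is(schedule, "DoseSchedule"))
  design@conditioningDays +
    (max(schedule@doseDays) - design@firstDoseDay) + design@followupDays
}

#' Assign study days to treatment cycles
#'
#' Cycle 0 is the conditioning window (`-conditioningDays .. 0`); cycle n
#' (n >= 1) spans days `interval*(n-1)+1 .. interval*n` with uniform bins by
#' default. The reference experiment's printed table uses slightly irregular
#' edges around the dose gap, so an explicit edge list can be supplied:
#' `edges[i]` is the last day of cycle i-1, i.e. cycles are
#' `(edges[i-1], edges[i]]`.
#'
#' @param day Integer vector of study days.
#' @param design A [StudyDesign-class].
#' @param edges Optional increasing vector of cycle upper edges starting with
#'   the edge of cycle 0 (e.g. `c(0, 14, 28, ...)`).
#' @return Integer cycle indices.
#' @export
assignCycle <- function(day, design, edges = NULL) {
  stopifnot(is(design, "StudyDesign"))
  span <- recordingSpan(design)
  lo <- design@firstDoseDay - design@conditioningDays
  hi <- lo + span
  if (any(day < lo | day > hi))
    stop("day outside the recording window [", lo, ", ", hi, "]")
  if (is.null(edges)) {
    ifelse(day <= 0L, 0L,
           as.integer(ceiling(day / design@doseIntervalDays)))
  } else {
    stopifnot(!is.unsorted(edges, strictly = TRUE))
    findInterval(day, edges, left.open = TRUE)
  }
}

#' Validate a plate layout against its capacity
#'
#' An over-capacity layout is a report outcome, not an error.
#'
#' @param layout A [PlateLayout-class].
#' @return A list with `valid`, `totalReactions` and `capacity`.
#' @examples
#' validatePlate(PlateLayout(18, 3, 56))$totalReactions # 3024
#' @export
validatePlate <- function(layout) {
  stopifnot(is(layout, "PlateLayout"))
  total <- layout@nAssays * layout@nReplicates * layout@nSamples
  list(valid = total <= layout@capacity,
       totalReactions = total, capacity = layout@capacity)
}

# ---------------------------------------------------------------------------
# External interfaces
# ---------------------------------------------------------------------------

#' Read a StudyDesign from a YAML or JSON config file
#'
#' Keys mirror the arguments of [StudyDesign()] (snake_case accepted).
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return A [StudyDesign-class].
#' @export
readStudyDesign <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # tolerate snake_case keys
  names(cfg) <- gsub("_(\\w)", "\\U\\1", names(cfg), perl = TRUE)
  ok <- intersect(names(cfg), names(formals(StudyDesign)))
  do.call(StudyDesign, cfg[ok])
}

#' Write a DoseSchedule as a two-column CSV
#'
#' @param schedule A [DoseSchedule-class].
#' @param path Output CSV path (columns `dose_index`, `day`).
#' @return `path`, invisibly.
#' @export
writeDoseSchedule <- function(schedule, path) {
  stopifnot(is(schedule, "DoseSchedule"))
  utils::write.csv(
    data.frame(dose_index = seq_along(schedule@doseDays),
               day = schedule@doseDays),
    path, row.names = FALSE)
  invisible(path)
}
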