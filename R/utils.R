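`%||%` <- function(a, b) if (is.null(a)) b else a

.assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  x
}

.assertNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  as.numeric(x)
}

.assertCount <- function(x, name, lower = 0L) {
  x <- .assertNumber(x, name, lower = lower)
  if (x != round(x)) stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  as.integer(x)
}

# Text representation for waveform tables: round-trips doubles exactly, so
# write -> read -> write is byte-identical.
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.eyeLevels <- c("OD", "OS")
.labelLevels <- c("ON_POS", "ON_NEG", "UNKNOWN")
.eyeClassLevels <- c("on_acute", "on_chronic", "control_fellow",
                     "control_patient", "control_healthy", "unknown")

# label implied by an eye_class value
.labelForEyeClass <- function(eye_class) {
  ifelse(eye_class %in% c("on_acute", "on_chronic"), "ON_POS",
         ifelse(eye_class == "unknown", "UNKNOWN", "ON_NEG"))
}

.recordId <- function(subject_id, eye, visit_index, recording_index) {
  sprintf("%s:%s:v%d:r%d", subject_id, eye,
          as.integer(visit_index), as.integer(recording_index))
}
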