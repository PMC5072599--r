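#' Muscles modeled by the ankle plantarflexor set
#'
#' The model tracks the major surface-measurable ankle plantarflexors: the
#' triceps surae (soleus, medial and lateral gastrocnemius), the peroneus
#' longus, and the combined flexor digitorum/hallucis longus (FDHL). Only the
#' FDHL is treated as multiarticular across the ankle, longitudinal arch, and
#' metatarsophalangeal (MTP) joints.
#'
#' @format character vector of the five required muscle names.
#' @export
required_muscles <- c("soleus", "gastroc_med", "gastroc_lat", "peroneus", "fdhl")

#' Default muscle-parameter table
#'
#' Anthropometric constants per muscle: physiological cross-sectional area
#' (PCSA, cm^2), fiber pennation angle (rad), sagittal moment arm about the
#' ankle (m, plantarflexion-positive) and about the MTP joint (m, nonzero only
#' for the FDHL). Values are literature-informed, configurable placeholders of
#' typical adult magnitudes; any study should substitute its own parameter set
#' via [make_muscle_set()].
#'
#' @return data.frame with columns `name`, `pcsa`, `pennation`, `r_ankle`,
#'   `r_mtp`.
#' @export
default_muscle_table <- function() {
  data.frame(
    name      = required_muscles,
    pcsa      = c(52,    21,    10,    10,    11),      # cm^2
    pennation = c(0.44,  0.30,  0.14,  0.17,  0.24),    # rad
    r_ankle   = c(0.050, 0.050, 0.050, 0.025, 0.035),   # m
    r_mtp     = c(0,     0,     0,     0,     0.008),   # m
    stringsAsFactors = FALSE
  )
}

#' Build and validate a muscle set
#'
#' Validates a muscle-parameter table against the model's requirements: the
#' five modeled plantarflexors must all be present, PCSA positive, pennation
#' in `[0, pi/2)`, ankle moment arms positive, and MTP moment arms zero for
#' every muscle except the FDHL.
#'
#' @param config_table data.frame with columns `name`, `pcsa`, `pennation`,
#'   `r_ankle`, `r_mtp` (see [default_muscle_table()]).
#' @return A `muscle_set` (validated data.frame).
#' @export
#' @examples
#' ms <- make_muscle_set(default_muscle_table())
#' muscle_gain(ms[ms$name == "soleus", ])  # PCSA * cos(pennation)
make_muscle_set <- function(config_table = default_muscle_table()) {
  need <- c("name", "pcsa", "pennation", "r_ankle", "r_mtp")
  miss_col <- setdiff(need, names(config_table))
  if (length(miss_col))
    stop("muscle table is missing column(s): ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  tab <- config_table[need]
  unknown <- setdiff(tab$name, required_muscles)
  if (length(unknown))
    stop("unknown muscle name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing_m <- setdiff(required_muscles, tab$name)
  if (length(missing_m))
    stop("configuration error: missing required muscle(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$name))
    stop("duplicated muscle name(s) in table", call. = FALSE)
  if (any(tab$pcsa <= 0))
    stop("validation error: PCSA must be positive for all muscles", call. = FALSE)
  if (any(tab$pennation < 0 | tab$pennation >= pi / 2))
    stop("pennation angles must lie in [0, pi/2) rad", call. = FALSE)
  if (any(tab$r_ankle <= 0))
    stop("ankle moment arms must be positive (plantarflexion-positive)",
         call. = FALSE)
  if (any(tab$r_mtp[tab$name != "fdhl"] != 0))
    stop("r_mtp must be zero for every muscle except the fdhl", call. = FALSE)
  tab <- tab[match(required_muscles, tab$name), ]
  rownames(tab) <- NULL
  class(tab) <- c("muscle_set", "data.frame")
  tab
}

#' Effective EMG-to-force gain of a muscle
#'
#' `PCSA * cos(pennation)`: the along-tendon force per unit of normalized
#' excitation and per unit of the trial scaling constant C.
#'
#' @param muscle one row of a `muscle_set` (or a data.frame of rows).
#' @return numeric gain(s), cm^2.
#' @export
muscle_gain <- function(muscle) muscle$pcsa * cos(muscle$pennation)

# internal: fetch one muscle row by name
muscle_row <- function(muscles, name) {
  i <- match(name, muscles$name)
  if (is.na(i)) stop("configuration error: muscle '", name,
                     "' not present in muscle set", call. = FALSE)
  muscles[i, ]
}
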