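# Whole-body blood circulation as parallel flow-weighted compartments.
# Visit probability is proportional to compartment blood flow Q_o and the
# residence per visit has mean V_o/Q_o, which makes the stationary occupancy
# proportional to blood volume V_o -- the behaviour the ICRP 89 reference
# circulation implies.

.sex_reference <- list(
  male   = list(total_blood_volume = 5.3, cardiac_output = 6.5),
  female = list(total_blood_volume = 3.9, cardiac_output = 5.9)
)

#' Read a compartment parameter table
#'
#' Reads a CSV with columns `compartment`, `volume_fraction`, `flow_fraction`
#' and `in_field`, giving per-compartment blood volume and blood flow as
#' fractions of the sex-specific total blood volume and cardiac output.
#'
#' @param path path to the CSV file. The default is the table shipped with
#'   the package, adapted from ICRP Publication 89 reference values for the
#'   compartments used in head-and-neck blood-dose estimation.
#' @return a data.frame with one row per compartment.
#' @export
read_compartment_table <- function(path = system.file("extdata", "icrp89_compartments.csv",
                                                      package = "circdose", mustWork = TRUE)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compartment", "volume_fraction", "flow_fraction", "in_field")
  if (!all(need %in% names(tab))) {
    stop("compartment table must have columns: ", paste(need, collapse = ", "))
  }
  tab$in_field <- as.logical(tab$in_field)
  tab
}

#' Build a sex-specific reference circulation model
#'
#' Scales a compartment parameter table to the sex-specific reference total
#' blood volume and cardiac output (male: 5.3 L and 6.5 L/min; female: 3.9 L
#' and 5.9 L/min, from ICRP Publication 89). If the fractions do not sum to
#' one, a `residual_body` compartment absorbs the remainder so that both
#' conservation sums close exactly.
#'
#' @param sex `"male"` or `"female"`.
#' @param params compartment parameter table (see
#'   [read_compartment_table()]); fractions are relative to the sex-specific
#'   totals.
#' @return an object of class `circulation_model` with elements
#'   `sex`, `compartments` (data.frame with `name`, `blood_volume` \[mL\],
#'   `blood_flow` \[mL/min\], `in_field`), `total_blood_volume` \[L\] and
#'   `cardiac_output` \[L/min\].
#' @examples
#' m <- circulation_model("male")
#' sum(m$compartments$blood_volume)  # 5300 mL
#' @export
circulation_model <- function(sex = c("male", "female"), params = read_compartment_table()) {
  sex <- match.arg(sex)
  ref <- .sex_reference[[sex]]
  if (!is.data.frame(params) || nrow(params) == 0) {
    stop("'params' must be a non-empty compartment table")
  }
  if (anyDuplicated(params$compartment)) {
    stop("duplicate compartment names: ",
         paste(unique(params$compartment[duplicated(params$compartment)]), collapse = ", "))
  }
  vf <- params$volume_fraction
  ff <- params$flow_fraction
  if (any(!is.finite(vf)) || any(!is.finite(ff)) || any(vf < 0) || any(ff < 0)) {
    stop("volume and flow fractions must be finite and non-negative")
  }
  tol <- 1e-9
  if (sum(vf) > 1 + tol) stop("volume fractions sum to more than 1 (", signif(sum(vf), 6), ")")
  if (sum(ff) > 1 + tol) stop("flow fractions sum to more than 1 (", signif(sum(ff), 6), ")")

  # residual closure: the residual_body row (created if absent) absorbs the
  # remainder so both sums equal the reference totals exactly
  res_v <- 1 - sum(vf[params$compartment != "residual_body"])
  res_f <- 1 - sum(ff[params$compartment != "residual_body"])
  if ("residual_body" %in% params$compartment) {
    i <- match("residual_body", params$compartment)
    vf[i] <- res_v
    ff[i] <- res_f
  } else if (res_v > tol || res_f > tol) {
    params <- rbind(params, data.frame(compartment = "residual_body",
                                       volume_fraction = res_v, flow_fraction = res_f,
                                       in_field = TRUE))
    vf <- c(vf, res_v)
    ff <- c(ff, res_f)
  }
  if (any(vf <= 0) || any(ff <= 0)) {
    bad <- params$compartment[vf <= 0 | ff <= 0]
    stop("non-positive blood volume or flow for compartment(s): ",
         paste(bad, collapse = ", "))
  }

  comps <- data.frame(name = params$compartment,
                      blood_volume = vf * ref$total_blood_volume * 1000,
                      blood_flow = ff * ref$cardiac_output * 1000,
                      in_field = params$in_field,
                      stringsAsFactors = FALSE)
  structure(list(sex = sex,
                 compartments = comps,
                 total_blood_volume = ref$total_blood_volume,
                 cardiac_output = ref$cardiac_output),
            class = "circulation_model")
}

#' Build a circulation model from absolute compartment values
#'
#' Constructs a model directly from absolute blood volumes and flows; the
#' totals are the sums of the supplied values. Intended for toy and test
#' models where the sex-specific reference totals are not wanted.
#'
#' @param name compartment names (unique).
#' @param blood_volume blood volume per compartment, mL (> 0).
#' @param blood_flow blood flow per compartment, mL/min (> 0).
#' @param in_field logical; whether a plan may assign the compartment a DVH.
#' @param sex label only; does not rescale anything here.
#' @return a `circulation_model`.
#' @export
custom_circulation_model <- function(name, blood_volume, blood_flow,
                                     in_field = TRUE, sex = "male") {
  n <- length(name)
  stopifnot(length(blood_volume) == n, length(blood_flow) == n)
  in_field <- rep_len(as.logical(in_field), n)
  if (anyDuplicated(name)) stop("duplicate compartment names")
  if (any(blood_volume <= 0) || any(blood_flow <= 0)) {
    stop("non-positive blood volume or flow for compartment(s): ",
         paste(name[blood_volume <= 0 | blood_flow <= 0], collapse = ", "))
  }
  comps <- data.frame(name = name, blood_volume = blood_volume,
                      blood_flow = blood_flow, in_field = in_field,
                      stringsAsFactors = FALSE)
  structure(list(sex = sex, compartments = comps,
                 total_blood_volume = sum(blood_volume) / 1000,
                 cardiac_output = sum(blood_flow) / 1000),
            class = "circulation_model")
}

#' Mean transit time per compartment
#'
#' The mean residence time of blood in each compartment,
#' `60 * blood_volume / blood_flow` seconds.
#'
#' @param model a `circulation_model`.
#' @return named numeric vector of transit times in seconds.
#' @export
transit_time <- function(model) {
  stopifnot(inherits(model, "circulation_model"))
  cmp <- model$compartments
  if (any(cmp$blood_flow <= 0)) {
    stop("zero or negative blood flow for compartment(s): ",
         paste(cmp$name[cmp$blood_flow <= 0], collapse = ", "))
  }
  stats::setNames(60 * cmp$blood_volume / cmp$blood_flow, cmp$name)
}

#' Stationary occupancy probabilities
#'
#' In the flow-weighted parallel model (visit probability proportional to
#' blood flow, mean residence `V/Q`), the stationary probability of finding a
#' blood particle in a compartment is its share of the total blood volume.
#'
#' @param model a `circulation_model`.
#' @return named numeric vector of probabilities summing to 1.
#' @export
steady_state_occupancy <- function(model) {
  stopifnot(inherits(model, "circulation_model"))
  cmp <- model$compartments
  stats::setNames(cmp$blood_volume / sum(cmp$blood_volume), cmp$name)
}

#' Validate a circulation model
#'
#' Checks positivity of volumes and flows and the two conservation sums
#' (compartment volumes against total blood volume, flows against cardiac
#' output, both to 0.1%).
#'
#' @param model a `circulation_model`.
#' @return character vector of violations; empty if the model is valid.
#' @export
validate_circulation <- function(model) {
  stopifnot(inherits(model, "circulation_model"))
  cmp <- model$compartments
  out <- character(0)
  for (i in seq_len(nrow(cmp))) {
    if (!is.finite(cmp$blood_volume[i]) || cmp$blood_volume[i] <= 0) {
      out <- c(out, sprintf("compartment '%s': non-positive blood_volume", cmp$name[i]))
    }
    if (!is.finite(cmp$blood_flow[i]) || cmp$blood_flow[i] <= 0) {
      out <- c(out, sprintf("compartment '%s': non-positive blood_flow", cmp$name[i]))
    }
  }
  vtot <- model$total_blood_volume * 1000
  qtot <- model$cardiac_output * 1000
  if (abs(sum(cmp$blood_volume) - vtot) > 1e-3 * vtot) {
    out <- c(out, sprintf("blood volume sum %.1f mL differs from total %.1f mL by more than 0.1%%",
                          sum(cmp$blood_volume), vtot))
  }
  if (abs(sum(cmp$blood_flow) - qtot) > 1e-3 * qtot) {
    out <- c(out, sprintf("blood flow sum %.1f mL/min differs from cardiac output %.1f mL/min by more than 0.1%%",
                          sum(cmp$blood_flow), qtot))
  }
  out
}

#' @export
print.circulation_model <- function(x, ...) {
  cat(sprintf("Circulation model (%s): %d compartments, %.1f L blood, %.1f L/min cardiac output\n",
              x$sex, nrow(x$compartments), x$total_blood_volume, x$cardiac_output))
  tt <- transit_time(x)
  df <- x$compartments
  df$transit_s <- round(tt, 2)
  df$blood_volume <- round(df$blood_volume, 1)
  df$blood_flow <- round(df$blood_flow, 1)
  print(df, row.names = FALSE)
  invisible(x)
}
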