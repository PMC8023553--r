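# Run configuration: defaults, validation, YAML loading.

#' Default run configuration
#'
#' Surface classification uses a 0.20 monomer-RSA cutoff and a 5 Angstrom
#' interchain distance; ASA sampling uses a 1.4 A probe and 960 points per
#' atom; interaction thresholds follow the BINANA-style defaults.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    rsa_cutoff = 0.20,
    interface_cutoff = 5.0,
    probe_radius = 1.4,
    asa_points = 960,
    background = "blosum62",
    fold = NULL,
    rel_asa_convention = "literal",
    correction = TRUE,
    his_charged = FALSE,
    contact_enumeration_cutoff = 5.0,
    thresholds = list(
      close_short = 2.5, close_long = 4.0, hydrophobic = 4.0,
      hbond_dist = 4.0, hbond_angle_dev = 40, salt_bridge = 5.5,
      pi_pi_dist = 7.5, pi_pi_angle = 30, t_stack_dist = 5.0,
      t_stack_angle_dev = 30, cation_pi_dist = 6.0, ring_pad = 0.75),
    seed = 1)
}

#' Validate and normalize a configuration
#'
#' Merges user values over the defaults, warns about (and drops) unknown
#' keys, and collects every violation into a single error.
#'
#' @param config named list of overrides, a YAML file path, or `NULL` for
#'   pure defaults.
#' @return the normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  base <- default_config()
  if (is.null(config) || length(config) == 0) return(base)
  if (!is.list(config)) stop("config must be a named list or YAML path")

  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
    config <- config[setdiff(names(config), unknown)]
  }
  if (!is.null(config$thresholds)) {
    tun <- setdiff(names(config$thresholds), names(base$thresholds))
    if (length(tun)) {
      warning("unknown threshold key(s) ignored: ",
              paste(tun, collapse = ", "))
      config$thresholds <- config$thresholds[
        setdiff(names(config$thresholds), tun)]
    }
  }
  cfg <- utils::modifyList(base, config)

  problems <- character(0)
  for (k in c("rsa_cutoff", "interface_cutoff", "probe_radius"))
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      problems <- c(problems, paste0(k, " must be a positive number"))
  if (!is.numeric(cfg$asa_points) || cfg$asa_points < 16)
    problems <- c(problems, "asa_points must be >= 16")
  for (k in names(cfg$thresholds))
    if (!is.numeric(cfg$thresholds[[k]]) || cfg$thresholds[[k]] <= 0)
      problems <- c(problems, paste0("thresholds$", k,
                                     " must be a positive number"))
  if (!is.null(cfg$fold) &&
      !cfg$fold %in% c("alpha_helical", "beta_barrel"))
    problems <- c(problems, "fold must be alpha_helical or beta_barrel")
  if (!cfg$rel_asa_convention %in% c("literal", "buried_fraction"))
    problems <- c(problems,
                  "rel_asa_convention must be literal or buried_fraction")
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  cfg
}
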