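#' Relaxation-rate scans over the left reservoir density
#'
#' Reproduces the figure-level computation behind the dynamical-transition
#' analysis: lambda_1 as a function of rhoL at fixed rhoR, for any subset of
#' the methods (pair approximation at one or more sizes, DWT, mDWT, exact
#' finite-size + BST extrapolation), merged into one long-format table.
#'
#' @param config list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{V}{repulsion (or `"2vstar"` for 2 V*)}
#'     \item{rhoR}{right reservoir density (scalar)}
#'     \item{rhoL}{vector of left reservoir densities}
#'     \item{methods}{subset of `"pa"`, `"dwt"`, `"mdwt"`, `"exact+bst"`}
#'     \item{N}{vector of chain lengths for the PA}
#'     \item{N_exact}{lengths for the exact-gap pipeline (default 4:10)}
#'     \item{omega}{BST exponent (default 2)}
#'     \item{mdwt_rule}{plateau rule (default "max-plateau")}
#'     \item{out}{optional CSV output path}
#'   }
#' @return data frame with columns V, rhoL, rhoR, N, method, lambda1,
#'   is_complex, status
#' @export
run_lambda_scan <- function(config) {
  cfg <- load_config(config)
  rates <- config_rates(cfg)
  rhoL <- as.numeric(cfg$rhoL)
  if (length(rhoL) == 0) {
    warning("empty rhoL grid: returning empty table")
    return(data.frame())
  }
  methods <- cfg$methods %||% c("pa", "dwt")
  rows <- list()
  emit <- function(rL, N, method, lambda1, is_complex = FALSE,
                   status = "ok") {
    rows[[length(rows) + 1]] <<- data.frame(
      V = rates$V, rhoL = rL, rhoR = cfg$rhoR, N = N, method = method,
      lambda1 = lambda1, is_complex = is_complex, status = status)
  }
  if ("pa" %in% methods) {
    for (N in as.integer(cfg$N %||% 50)) {
      for (rL in rhoL) {
        res <- tryCatch({
          bc <- boundary_conditions(rL, cfg$rhoR, rates)
          sr <- slowest_rate(find_ness(bc, N), bc, check_fixed_point = FALSE)
          emit(rL, N, "pa", sr$lambda1, sr$is_complex)
        }, error = function(e) emit(rL, N, "pa", NA_real_,
                                    status = conditionMessage(e)))
      }
    }
  }
  if ("dwt" %in% methods)
    for (rL in rhoL)
      emit(rL, NA_integer_, "dwt", dwt_lambda1(rL, cfg$rhoR, rates))
  if ("mdwt" %in% methods) {
    res <- tryCatch({
      m <- mdwt_rate(rhoL, cfg$rhoR, rates,
                     rule = cfg$mdwt_rule %||% "max-plateau")
      for (j in seq_along(rhoL))
        emit(rhoL[j], NA_integer_, "mdwt", m$lambda1[j])
    }, error = function(e)
      for (rL in rhoL) emit(rL, NA_integer_, "mdwt", NA_real_,
                            status = conditionMessage(e)))
  }
  if ("exact+bst" %in% methods) {
    for (rL in rhoL) {
      res <- tryCatch({
        bc <- boundary_conditions(rL, cfg$rhoR, rates)
        pipe <- gap_extrapolation_pipeline(bc,
                                           N_range = cfg$N_exact %||% 4:10,
                                           omega = cfg$omega %||% 2)
        emit(rL, NA_integer_, "exact+bst", pipe$limit,
             status = if (pipe$reliable) "ok" else "unreliable")
      }, error = function(e) emit(rL, NA_integer_, "exact+bst", NA_real_,
                                  status = conditionMessage(e)))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(cfg$out)) utils::write.csv(out, cfg$out, row.names = FALSE)
  out
}

#' NESS phase diagram with dynamical-transition lines
#'
#' Combines the extremal-current phase raster with the mDWT transition
#' lines (first-maximum analogue plus min-plateau bounds where applicable),
#' mirrored into the LD phases by particle-hole symmetry.
#'
#' @param config list or YAML path with fields `V`, `rho_grid` (raster
#'   resolution), `rhoR_lines` (rhoR grid for the transition lines),
#'   `out_raster`, `out_lines` (optional CSV paths)
#' @return list with `raster` and `lines` data frames
#' @export
run_phase_diagram <- function(config) {
  cfg <- load_config(config)
  rates <- config_rates(cfg)
  grid <- cfg$rho_grid %||% seq(0.02, 0.98, by = 0.02)
  raster <- phase_raster(rates, grid, grid, file = cfg$out_raster)
  lines <- NULL
  if (!is.null(cfg$rhoR_lines))
    lines <- dwt_transition_lines(rates, cfg$rhoR_lines,
                                  file = cfg$out_lines)
  list(raster = raster, lines = lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    cfg <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    cfg <- config
  } else stop("config must be a list or a YAML file path")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num_in_01 <- function(x) is.null(x) || (is.numeric(x) && all(x >= 0) && all(x <= 1))
  if (!num_in_01(cfg$rhoL) || !num_in_01(cfg$rhoR))
    stop("config: rhoL/rhoR must be numeric within [0, 1]")
  known <- c("pa", "dwt", "mdwt", "exact+bst", "kmc")
  if (!is.null(cfg$methods) && !all(cfg$methods %in% known))
    stop("config: unknown method(s) ",
         paste(setdiff(cfg$methods, known), collapse = ", "))
  invisible(cfg)
}

config_rates <- function(cfg) {
  V <- cfg$V %||% 0
  if (identical(V, "2vstar")) V <- 2 * kls_vstar_exact()
  if (identical(V, "vstar")) V <- kls_vstar_exact()
  if (identical(cfg$family %||% "glauber", "tasep")) tasep_rates()
  else if (identical(cfg$family %||% "glauber", "as")) as_rates(as.numeric(V))
  else glauber_rates(as.numeric(V))
}
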