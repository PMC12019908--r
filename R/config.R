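#' Default pipeline configuration
#'
#' Every tunable threshold of the analysis, with its standard value:
#' digestion windows and missed-cleavage limits per approach, protease
#' regimes, the charge model (pH 7.0, EMBOSS pKa set; the culture pH 7.2
#' is available by setting `charge$pH`), the selection quantiles (top /
#' bottom 10% extremeness, top 50% abundance), the cluster count (9), the
#' COG reporting floor (2%) and the secreted-biomass coverage thresholds
#' (50% and 75%).
#'
#' @param ... Named overrides for top-level entries.
#' @return Nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    digestion = list(
      ibaq_length_range = c(7L, 30L),
      max_missed = list(whole = 2L, shaved = 4L, supernatant = 2L),
      mode = list(whole = "specific", shaved = "semispecific",
                  supernatant = "specific")
    ),
    proteases = list(whole = "trypsin", shaved = "trypsin",
                     supernatant = "trypsin"),
    charge = list(pH = 7.0, pka = as.list(emboss_pka())),
    selection = list(quantile = 0.10, abundance_quantile = 0.50),
    clustering = list(k = 9L),
    cog = list(other_floor = 0.02),
    coverage = list(thresholds = c(0.5, 0.75))
  )
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Missing entries fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge_cfg(base[[k]], over[[k]])
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  merge_cfg(cfg, user)
}

#' Write a pipeline configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
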