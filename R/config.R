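#' Pipeline configuration defaults
#'
#' Nested configuration covering every stage. The reference settings are
#' the defaults: 12-layer/8-head/512-wide encoder with 3 parallel branches,
#' 64-step diffusion, 70/15/15 splits, batch 64, 100 epochs, initial
#' learning rate 0.001 decayed 10% every 10 epochs, dropout 0.1 and L2
#' 1e-4, composite loss weights (1.0, 0.5, 0.1). Any element can be
#' overridden with a nested list or a YAML file ([read_config()]).
#'
#' @param ... named nested overrides, e.g.
#'   \code{model = list(layers = 2)}.
#' @return nested list of class \code{leafpad_config}.
#' @export
leafpad_config <- function(...) {
  cfg <- list(
    model = list(layers = 12L, heads = 8L, head_dim = 64L, ffn_hidden = 2048L,
                 branches = 3L, fusion = "weighted_sum",
                 attention_mode = "parallel", image_size = 64L, patch = 8L,
                 channels = 3L, n_classes = 6L, dropout = 0.1),
    train = list(epochs = 100L, batch = 64L, base_lr = 0.001,
                 optimizer = "adam", momentum = 0.9, weight_decay = 1e-4,
                 protocol = "holdout"),
    loss = list(mode = "parallel", gamma = 2,
                weights = c(cls = 1.0, recon = 0.5, adv = 0.1)),
    augment = list(p = 0.5, area = c(0.1, 0.4),
                   ops = c("cutout", "cutmix", "mosaic"),
                   diffusion_ratio = 0.25),
    diffusion = list(T = 64L, convention = "literal", alpha_start = 0.999,
                     alpha_end = 0.95, width = 128L, body = 2L),
    split = list(ratios = c(0.7, 0.15, 0.15), stratify = TRUE)
  )
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- "leafpad_config"
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read / write a pipeline configuration as YAML
#'
#' The file holds nested overrides of [leafpad_config()]; missing entries
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return [leafpad_config()] list.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  cfg <- merge_config(leafpad_config(), over)
  class(cfg) <- "leafpad_config"
  cfg
}

#' @rdname read_config
#' @param cfg configuration to write.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# the model sub-config as an attention_config
model_attention_config <- function(cfg) {
  m <- cfg$model
  attention_config(layers = m$layers, heads = m$heads, head_dim = m$head_dim,
                   ffn_hidden = m$ffn_hidden, branches = m$branches,
                   fusion = m$fusion, attention_mode = m$attention_mode,
                   image_size = m$image_size, patch = m$patch,
                   channels = m$channels, n_classes = m$n_classes,
                   dropout = m$dropout)
}
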