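# A stub model with scripted validation losses, plugged into the trainer's
# S3 seam to test the scheduling logic in isolation.

register_stub <- function(val_losses) {
  env <- new.env()
  env$epoch <- 0L
  env$restored <- NULL
  env$lrs <- numeric(0)
  registerS3method("vf_fit_batch", "vf_stub",
                   function(model, samples, lr, config) {
                     e <- get("env", envir = attr(model, "store"))
                     e$lrs <- c(e$lrs, lr)
                     1.0
                   }, envir = asNamespace("voxflex"))
  registerS3method("vf_val_loss", "vf_stub",
                   function(model, samples, config) {
                     e <- get("env", envir = attr(model, "store"))
                     e$epoch <- e$epoch + 1L
                     val_losses[min(e$epoch, length(val_losses))]
                   }, envir = asNamespace("voxflex"))
  registerS3method("vf_checkpoint", "vf_stub",
                   function(model) {
                     e <- get("env", envir = attr(model, "store"))
                     list(at_epoch = e$epoch)
                   }, envir = asNamespace("voxflex"))
  registerS3method("vf_restore", "vf_stub",
                   function(model, state) {
                     e <- get("env", envir = attr(model, "store"))
                     e$restored <- state
                     invisible(model)
                   }, envir = asNamespace("voxflex"))
  store <- new.env(); assign("env", env, envir = store)
  model <- structure(list(), class = "vf_stub", store = store)
  list(model = model, env = env)
}

# a minimal synthetic sample box for schedule/loss tests
stub_box <- function(seed = 1, C = 2) {
  set.seed(seed)
  sb <- list(channels = array(runif(40^3 * C), c(40, 40, 40, C)),
             label = array(rnorm(1000), c(10, 10, 10)),
             mask = array(runif(1000) < 0.3, c(10, 10, 10)),
             occ = array(as.integer(runif(40^3) < 0.1), c(40, 40, 40)),
             grid_index = c(0, 0, 0))
  class(sb) <- "sample_box"
  sb
}
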