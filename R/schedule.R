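# Trial schedules for the four-phase generalization protocol.

.WORKSPACES <- c("training", "test1", "test2")

#' Build the four-phase trial schedule of an experiment
#'
#' Phases and counts: familiarization (16 null-field trials, training
#' workspace), pre-exposure (384 trials: 4 null-field and 4 force-channel
#' repetitions per direction per workspace, in 4 uniformly shuffled blocks),
#' exposure (240 force-field trials: 15 blocks of the 16 directions,
#' training workspace), generalization (1920 trials: 1536 force-field trials
#' in the training workspace interleaved 4:1 with 384 force-channel trials —
#' 8 repetitions x 16 directions x 3 workspaces — each channel trial placed
#' uniformly within its series of four field trials).
#'
#' Counts are invariant across seeds; only the within-block ordering varies.
#'
#' @param id Experiment id (1..4); recorded in the output.
#' @param seed Integer seed for the uniform randomizations.
#' @return Data frame with columns `trial`, `phase`, `workspace`,
#'   `condition` (`NF`/`FC`/`FF`), `direction` (deg) and `rep` (repetition
#'   index within phase x workspace x condition x direction).
#' @export
build_schedule <- function(id = 1, seed = 1L) {
  if (!id %in% 1:4) stop(sprintf("unknown experiment id '%s' (must be 1..4)", id))
  set.seed(seed)
  dirs <- standard_directions()

  fam <- data.frame(phase = "familiarization", workspace = "training",
                    condition = "NF", direction = sample(dirs))

  pre <- do.call(rbind, lapply(1:4, function(blk) {
    g <- expand.grid(workspace = .WORKSPACES, condition = c("NF", "FC"),
                     direction = dirs, stringsAsFactors = FALSE)
    g <- g[sample(nrow(g)), c("workspace", "condition", "direction")]
    cbind(phase = "pre_exposure", g)
  }))

  expo <- do.call(rbind, lapply(1:15, function(blk) {
    data.frame(phase = "exposure", workspace = "training", condition = "FF",
               direction = sample(dirs))
  }))

  ff_dirs <- unlist(lapply(1:96, function(blk) sample(dirs)))
  fc <- do.call(rbind, lapply(1:8, function(blk) {
    g <- expand.grid(workspace = .WORKSPACES, direction = dirs,
                     stringsAsFactors = FALSE)
    g[sample(nrow(g)), ]
  }))
  gen <- vector("list", 384L)
  for (s in 1:384) {
    series <- data.frame(phase = "generalization", workspace = "training",
                         condition = "FF",
                         direction = ff_dirs[(4 * s - 3):(4 * s)])
    slot <- sample.int(5L, 1L)
    fc_row <- data.frame(phase = "generalization",
                         workspace = fc$workspace[s], condition = "FC",
                         direction = fc$direction[s])
    rest <- if (slot <= 4L) series[slot:4L, , drop = FALSE] else series[0L, ]
    gen[[s]] <- rbind(series[seq_len(slot - 1L), , drop = FALSE], fc_row, rest)
  }
  gen <- do.call(rbind, gen)

  out <- rbind(fam, pre, expo, gen)
  out$trial <- seq_len(nrow(out))
  key <- paste(out$phase, out$workspace, out$condition, out$direction)
  out$rep <- stats::ave(seq_len(nrow(out)), key, FUN = seq_along)
  rownames(out) <- NULL
  attr(out, "experiment") <- as.integer(id)
  attr(out, "seed") <- as.integer(seed)
  out[, c("trial", "phase", "workspace", "condition", "direction", "rep")]
}
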