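# Shared fixtures: small in-memory phantom sets and manifests, built in code.

phantom_pairs <- function(n, size = 64L, base_seed = 0L, stage = "expanded") {
  lapply(seq_len(n), function(i) {
    generate_frame(phantom_params(image_size = size, stage = stage,
                                  seed = base_seed + i))
  })
}

frames_of <- function(pairs) lapply(pairs, `[[`, "frame")
masks_of <- function(pairs) lapply(pairs, `[[`, "mask")

# in-memory manifest (list-columns frame/mask) spanning several patients
memory_manifest <- function(n_patients, frames_per_patient, size = 64L,
                            base_seed = 0L, stage = "expanded") {
  rows <- list()
  k <- 0L
  for (p in seq_len(n_patients)) {
    for (f in seq_len(frames_per_patient)) {
      k <- k + 1L
      fm <- generate_frame(phantom_params(image_size = size, stage = stage,
                                          seed = base_seed + k))
      rows[[k]] <- tibble::tibble(
        frame_path = NA_character_, mask_path = NA_character_,
        patient_id = sprintf("P%02d", p), sequence_id = "S01",
        frame_index = f, stage = stage,
        frame = list(fm$frame), mask = list(fm$mask)
      )
    }
  }
  dplyr::bind_rows(rows)
}

tiny_fit <- function(pairs, size, epochs = 3L, seed = 1L,
                     loss = "cross_entropy", augment = FALSE,
                     base_filters = 8L, depth = 2L) {
  train_unet(
    build_unet(net_config(base_filters, depth, size, seed = seed)),
    frames_of(pairs), masks_of(pairs),
    train_config(epochs = epochs, augment = augment,
                 loss = loss_config(loss), seed = seed)
  )
}
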