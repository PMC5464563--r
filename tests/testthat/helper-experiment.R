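# One shared end-to-end phantom experiment, computed lazily and cached
# for the session: 12 training cases feed the ANN, 30 test cases are
# scored under both operating profiles.  Problem sizes (96^3 voxels,
# 5 nodules of 3-10 mm per case, 8 vessels) are the generator defaults.

.suite_cache <- new.env(parent = emptyenv())

get_detection_experiment <- function() {
  if (!is.null(.suite_cache$exp)) return(.suite_cache$exp)
  cfgA <- cad_config("A")
  cfgB <- cad_config("B")

  train <- phantom_suite(12, seed = 900)
  ts <- build_training_set(train, cfgA)
  model <- ann_train(ts$features, ts$labels,
                     ann_config(seed = 42, max_epochs = 300))
  cutoff <- select_cutoff(predict(model, ts$features), ts$labels,
                          max_tp_loss = 0.1)

  test <- phantom_suite(30, seed = 100)
  marksA <- list(); marksAnn <- list(); marksB <- list()
  truths <- list(); ids <- character(0)
  candA <- list(); candB <- list()
  for (cs in test) {
    runA <- run_case(cs$volume, config = cfgA, model = NULL)
    prob <- if (nrow(runA$candidates))
      predict(model, runA$features) else numeric(0)
    mA <- data.frame(case_id = runA$candidates$case_id,
                     x_mm = runA$candidates$x_mm,
                     y_mm = runA$candidates$y_mm,
                     z_mm = runA$candidates$z_mm,
                     probability = runA$candidates$score)
    marksA[[length(marksA) + 1L]] <- mA
    mAnn <- mA
    mAnn$probability <- prob
    marksAnn[[length(marksAnn) + 1L]] <- mAnn[prob >= cutoff, , drop = FALSE]
    runB <- run_case(cs$volume, config = cfgB, model = NULL)
    marksB[[length(marksB) + 1L]] <-
      data.frame(case_id = runB$candidates$case_id,
                 x_mm = runB$candidates$x_mm,
                 y_mm = runB$candidates$y_mm,
                 z_mm = runB$candidates$z_mm,
                 probability = runB$candidates$score)
    truths[[length(truths) + 1L]] <- truth_table(cs$truth,
                                                 cs$volume$spacing_mm)
    ids <- c(ids, cs$volume$case_id)
    candA[[length(candA) + 1L]] <- runA$candidates
    candB[[length(candB) + 1L]] <- runB$candidates
  }
  .suite_cache$exp <- list(
    model = model, cutoff = cutoff,
    marksA = do.call(rbind, marksA),
    marksAnn = do.call(rbind, marksAnn),
    marksB = do.call(rbind, marksB),
    truth = do.call(rbind, truths), case_ids = ids,
    candA = do.call(rbind, candA), candB = do.call(rbind, candB))
  .suite_cache$exp
}
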