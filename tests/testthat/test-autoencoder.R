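test_that("the default architecture matches the three-block VGG19 layout", {
  sp <- ae_spec()
  enc <- sp$encoder_layers
  shapes <- vapply(enc, function(l)
    if (l$kind == "conv") sprintf("%s:%d>%d(k%d)", l$name, l$in_ch, l$out_ch, l$k)
    else l$kind, character(1))
  expect_equal(shapes,
    c("conv0:3>3(k1)", "conv1_1:3>64(k3)", "conv1_2:64>64(k3)", "pool",
      "conv2_1:64>128(k3)", "conv2_2:128>128(k3)", "pool", "conv3_1:128>256(k3)"))
  dec <- sp$decoder_layers
  dshapes <- vapply(dec, function(l)
    if (l$kind == "conv") sprintf("%s:%d>%d(k%d)", l$name, l$in_ch, l$out_ch, l$k)
    else l$kind, character(1))
  expect_equal(dshapes,
    c("dconv3_1:256>128(k3)", "upsample", "dconv2_2:128>128(k3)",
      "dconv2_1:128>64(k3)", "upsample", "dconv1_2:64>64(k3)",
      "dconv1_1:64>3(k3)", "dconv0:3>3(k1)"))
  # decoder channel sequence mirrors the encoder's; pools == upsamples
  expect_equal(sum(shapes == "pool"), sum(dshapes == "upsample"))
  # final projection is linear, everything else ReLU
  expect_false(dec[[length(dec)]]$relu)
  expect_true(all(vapply(dec[-length(dec)], function(l)
    l$kind != "conv" || l$relu, logical(1))))
  expect_error(ae_spec(0), "1..5")
  # the documented parameter count of the default architecture
  expect_equal(ae_n_params(sp), 1110427L)
})

test_that("latent shape contract: C=256, (h,w)=(ceil(H/4),ceil(W/4))", {
  w <- ae_init_weights(ae_spec(), seed = 0)
  img <- matrix(runif(32 * 36), 32, 36)
  z <- ae_encode(img, w)
  expect_equal(dim(z), c(8L, 9L, 256L))
  expect_true(all(is.finite(z)))
  # odd sizes round up
  z2 <- ae_encode(matrix(runif(50 * 66), 50, 66), w)
  expect_equal(dim(z2)[1:2], c(13L, 17L))
})

test_that("decode(encode(x)) preserves spatial shape across sizes", {
  # width-1-channel instance: the spatial contract is pure pooling/upsampling
  # geometry, independent of channel width
  w <- ae_init_weights(ae_spec(width = 1e-4), seed = 1)
  for (H in seq(32L, 512L, by = 4L)) {
    x <- matrix(runif(H * 32L), H, 32L)
    y <- ae_decode(ae_encode(x, w), w)
    if (!identical(dim(y), dim(x))) fail(sprintf("shape broken at H=%d", H))
  }
  succeed()
  # a few non-square spot checks at full width off the 4-grid
  wf <- ae_init_weights(ae_spec(width = 0.05), seed = 1)
  for (sz in list(c(48L, 100L), c(35L, 61L), c(128L, 96L))) {
    x <- matrix(runif(prod(sz)), sz[1L], sz[2L])
    expect_equal(dim(ae_decode(ae_encode(x, wf), wf)), sz)
  }
})

test_that("encode is deterministic and mixing the latent with itself is exact", {
  w <- ae_init_weights(ae_spec(width = 0.1), seed = 2)
  x <- matrix(runif(64 * 64), 64, 64)
  z1 <- ae_encode(x, w); z2 <- ae_encode(x, w)
  expect_identical(unclass(z1), unclass(z2))
  zz <- matrix(0, 64, 64)
  expect_identical(unclass(ae_encode(zz, w)), unclass(ae_encode(zz, w)))
  # mix(f, f) = f exactly, so the decoded images are bitwise equal
  expect_identical(ae_decode(mix_features(z1, z1), w), ae_decode(z1, w))
})

test_that("mix_features is the element-wise mean", {
  w <- ae_init_weights(ae_spec(width = 0.05), seed = 3)
  f1 <- ae_encode(matrix(runif(32 * 32), 32, 32), w)
  f2 <- ae_encode(matrix(runif(32 * 32), 32, 32), w)
  expect_equal(unclass(mix_features(f1, f2)),
               (unclass(f1) + unclass(f2)) / 2, ignore_attr = TRUE)
  f0 <- f2; f0[] <- 0
  expect_equal(unclass(mix_features(f1, f0)), unclass(f1) / 2,
               ignore_attr = TRUE)
  f3 <- ae_encode(matrix(runif(64 * 64), 64, 64), w)
  expect_error(mix_features(f1, f3), "shapes differ")
})

test_that("decoding the zero latent yields a bias-determined constant image", {
  w <- ae_init_weights(ae_spec(width = 0.1), seed = 4)
  z <- ae_encode(matrix(runif(32 * 32), 32, 32), w)
  z0 <- unclass(z); z0[] <- 0
  z0 <- structure(z0, source_shape = c(32L, 32L), class = "latent_feature")
  img <- ae_decode(z0, w)
  expect_lt(diff(range(img)), 1e-12)
})

test_that("the packaged encoder matches a plain-R layer-by-layer re-implementation", {
  sp <- ae_spec(width = 0.03)  # channels 2,4,8 - tractable for the loop oracle
  w <- ae_init_weights(sp, seed = 5)
  set.seed(5)
  img <- matrix(runif(16 * 16), 16, 16)
  z <- ae_encode(img, w)
  zo <- oracle_encoder_forward(sp, w$encoder, img)
  expect_equal(unclass(z), zo, ignore_attr = TRUE, tolerance = 1e-10)
  # per-channel means agree too (the summary the contract quotes)
  expect_equal(apply(unclass(z), 3, mean), apply(zo, 3, mean), tolerance = 1e-10)
})

test_that("weights round-trip through the JSON archive", {
  w <- ae_init_weights(ae_spec(width = 0.05), seed = 6)
  f <- tempfile(fileext = ".json")
  ae_save_weights(w, f)
  w2 <- ae_load_weights(f)
  expect_equal(w2$encoder, w$encoder, tolerance = 1e-12)
  expect_equal(w2$decoder, w$decoder, tolerance = 1e-12)
  expect_equal(w2$spec$depth_blocks, w$spec$depth_blocks)
  # encode with reloaded weights is numerically identical
  x <- matrix(runif(32 * 32), 32, 32)
  expect_equal(unclass(ae_encode(x, w2)), unclass(ae_encode(x, w)),
               tolerance = 1e-12)
  expect_error(ae_load_weights(tempfile()), "no such file")
})

test_that("loading mismatched architectures names the offending layer", {
  w <- ae_init_weights(ae_spec(depth_blocks = 2, width = 0.05), seed = 7)
  f <- tempfile(fileext = ".json")
  ae_save_weights(w, f)
  # lie about the depth in the sidecar: first incompatible layer is named
  obj <- jsonlite::read_json(f, simplifyVector = FALSE)
  obj$depth_blocks <- 3
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_error(ae_load_weights(f), "conv2_2|conv3_1|layer")
})

test_that("decoding a latent with the wrong channel count is a configuration error", {
  w <- ae_init_weights(ae_spec(width = 0.05), seed = 8)
  bad <- structure(array(0, c(8, 8, 3)), source_shape = c(32L, 32L),
                   class = "latent_feature")
  expect_error(ae_decode(bad, w), "channels")
})
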