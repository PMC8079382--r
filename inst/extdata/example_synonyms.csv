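variant,canonical
travelgram,travel
instatravel,travel
igtravel,travel
travell,travel
travle,travel
naturee,nature
photografy,photography
fotography,photography
beautifull,beautiful
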