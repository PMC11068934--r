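cohort	depot	sex	genes	edges	key_drivers
STARNET	subcutaneous	male	7360	9174	833
GTEx	subcutaneous	male	6066	6782	695
STARNET	subcutaneous	female	6814	6865	753
GTEx	subcutaneous	female	5560	5651	632
STARNET	visceral	male	7343	8752	779
GTEx	visceral	male	6402	6845	670
STARNET	visceral	female	5908	5962	660
GTEx	visceral	female	4546	4533	502
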