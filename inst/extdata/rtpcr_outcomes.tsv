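outcome
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
confirmed
not_confirmed
not_confirmed
not_confirmed
assay_failed
assay_failed
assay_failed
assay_failed
assay_failed
assay_failed
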