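doc_id	text
ox1	The oxidized form of OxyR is a transcriptional activator of a multitude of genes that assist in protecting the cell from oxidative damage.
ox2	Activated OxyR then induces transcription of a set of antioxidant genes, including katG, ahpCF, dps, gorA, grxA and oxyS.
ox3	A hallmark of the E. coli response to hydrogen peroxide is the rapid and strong induction of a set of OxyR-regulated genes, including dps, katG, grxA, ahpCF and trxC.
bg1	Photosynthesis converts light into chemical energy inside chloroplasts.
bg2	Glacier retreat accelerated measurably during the last century.
bg3	The orchestra rehearsed a symphony before the winter concert.
bg4	Volcanic eruptions deposit ash layers across wide regions.
bg5	Ancient pottery fragments reveal trade routes between distant settlements.
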