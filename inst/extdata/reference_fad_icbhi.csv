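model,Bronchiectasis,Bronchiolitis,Healthy,Pneumonia,LRTI,URTI
mlpvae,28.40,11.72,4.81,12.34,3.16,14.11
cnnvae,12.47,10.86,12.05,11.56,12.10,10.44
cvae,13.96,10.88,12.07,11.62,10.79,10.57
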