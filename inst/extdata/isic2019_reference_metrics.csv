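model,class,auc,precision,accuracy,sensitivity,specificity
mobilenet_v2_radiomics_rf,AKIEC,73.9,73.9,76.9,77.6,99.5
mobilenet_v2_radiomics_rf,BCC,96.2,96.2,96.1,96.4,98.9
mobilenet_v2_radiomics_rf,BKL,90.8,90.8,92.2,91.9,99.4
mobilenet_v2_radiomics_rf,DF,76.7,76.7,68.8,69.5,100
mobilenet_v2_radiomics_rf,MEL,94.4,94.4,94.3,94.3,99.1
mobilenet_v2_radiomics_rf,NV,98.2,98.2,98.1,98.4,98.3
mobilenet_v2_radiomics_rf,SCC,75,75,73.8,73.9,98.7
mobilenet_v2_radiomics_rf,VASC,75.5,75.5,74,74.2,100
efficientnet_b4_radiomics_rf,AKIEC,74.7,74.7,74.7,75.4,99.3
efficientnet_b4_radiomics_rf,BCC,92.6,92.6,94,94.3,99.5
efficientnet_b4_radiomics_rf,BKL,92.4,92.4,93.1,92.8,99.2
efficientnet_b4_radiomics_rf,DF,64.9,64.9,50,50.4,100
efficientnet_b4_radiomics_rf,MEL,93.5,93.5,93.9,94.5,99.5
efficientnet_b4_radiomics_rf,NV,97.4,97.4,97.5,96.9,96.9
efficientnet_b4_radiomics_rf,SCC,79.3,79.3,76.2,76.4,99.6
efficientnet_b4_radiomics_rf,VASC,68.1,68.1,62.7,63.2,99.2
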